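LOCUS       SYNUNIT 550 bp    DNA     linear   SYN
DEFINITION  synthetic transcription unit (seeded generator, seed 42).
FEATURES             Location/Qualifiers
     promoter        1..120
     CDS             141..440
     polyA_signal    461..550
ORIGIN
        1 cctacactgt atatgccgaa cgttctaata aacgacttag caacaagtcg cctagaaagg
       61 taccgctggc atatcacgcc tcccgcttgc cgtcttcaac ttcatgaccc tcgtgcatca
      121 caaagcctca agccggagtc atgatgtcat tttaccatgt actctggatg ttggccactg
      181 tatactcagg agtccacgtg ttgattcaat acaacgtatc aagcagatct gtcctagacg
      241 caatttggtt aaaagcccgc gaaagtccct gggctgtagt tcccctcaga gactctgttc
      301 taaaggtgat agccaccatg acgcacgtgc ctcctcttcc gattgcgtcc cttcagccat
      361 ggcatgcatc tttaatgaca gtaagaaaat attgcgatgt ctatgaaata tgcggttcag
      421 acaagggatc tgacgcgtaa taggctttga aacagctgaa taaatcgtgt gaatacgtga
      481 gtcgtcggaa agcagttgaa tatctaacga cccctgcgca aggacacact agtcgccctt
      541 gagagcactc
//
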