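>SYNUNIT synthetic transcription unit (seeded generator, seed 42)
CCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGCAACAAGTCGCCTAGAAAGG
TACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCTCGTGCATCA
CAAAGCCTCAAGCCGGAGTCATGATGTCATTTTACCATGTACTCTGGATGTTGGCCACTG
TATACTCAGGAGTCCACGTGTTGATTCAATACAACGTATCAAGCAGATCTGTCCTAGACG
CAATTTGGTTAAAAGCCCGCGAAAGTCCCTGGGCTGTAGTTCCCCTCAGAGACTCTGTTC
TAAAGGTGATAGCCACCATGACGCACGTGCCTCCTCTTCCGATTGCGTCCCTTCAGCCAT
GGCATGCATCTTTAATGACAGTAAGAAAATATTGCGATGTCTATGAAATATGCGGTTCAG
ACAAGGGATCTGACGCGTAATAGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGA
GTCGTCGGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTT
GAGAGCACTC
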