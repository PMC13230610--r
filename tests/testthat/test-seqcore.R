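test_that("reverse complement matches published counter-primer pairs and is an involution", {
  expect_equal(unclass(revcomp(dna("ggttacgccgaacatgatc"))), "GATCATGTTCGGCGTAACC")
  expect_equal(unclass(revcomp(dna("ggttacccaggcctgcaaaaa"))), "TTTTTGCAGGCCTGGGTAACC")
  expect_equal(unclass(revcomp(dna(""))), "")
  set.seed(11)
  for (i in 1:25) {
    s <- dna(paste(sample(c("A", "C", "G", "T"), sample(1:80, 1), replace = TRUE),
                   collapse = ""))
    expect_identical(unclass(revcomp(revcomp(s))), unclass(s))
  }
})

test_that("dna() canonicalizes case and whitespace and rejects ambiguity codes", {
  expect_equal(unclass(dna("ac gT\n")), "ACGT")
  expect_error(dna("ACGN"), "non-ACGT")
  expect_error(dna("ACRT"), "non-ACGT")
})

test_that("translation follows the standard code, with stops as * and partial codons dropped", {
  expect_equal(translate_dna(dna("GAC")), "D")
  expect_equal(translate_dna(dna("AACTAT")), "NY")
  expect_equal(translate_dna(dna("TAA")), "*")
  expect_equal(translate_dna(dna("CTG")), "L")        # not an initiator context
  expect_equal(translate_dna(dna("GACTA")), "D")      # trailing partial dropped
  expect_equal(translate_dna(dna("AGACTA"), frame = 1), "D")
  expect_equal(translate_dna(dna("AGACTA"), frame = 2), "T")
  expect_error(translate_dna(dna("GA")), "too short")
})

test_that("codon choice tables validate against the genetic code", {
  tab <- midas_codon_table()
  expect_length(tab$codons, 20L)
  for (aa in names(tab$codons)) {
    expect_equal(translate_dna(dna(tab$codons[[aa]])), aa)
  }
  bad <- stats::setNames(tab$codons, rev(names(tab$codons)))
  expect_error(codon_choice_table(bad), "do not translate")
  expect_error(codon_choice_table(tab$codons[-1]), "exactly the 20")
})

test_that("nearest-neighbor Tm reproduces independently computed reference values", {
  # frozen references computed with an independent NN implementation
  # (unified 1998 parameter set, 50 mM Na+, 500 nM total strand)
  expect_equal(melting_temperature(dna("ACGTACGTACGTACGTACGT")), 57.0595,
               tolerance = 0.002)
  expect_equal(melting_temperature(dna("GGTTACGCCGAACATGATC")), 54.1666,
               tolerance = 0.002)
  expect_equal(melting_temperature(dna("TTTTTGCAGGCCTGGGTAACC")), 58.5217,
               tolerance = 0.002)
})

test_that("Tm respects duplex physics: GC > AT, strand symmetry, terminal-pair ordering", {
  expect_gt(melting_temperature(dna(strrep("G", 20))),
            melting_temperature(dna(strrep("A", 20))))
  set.seed(7)
  for (i in 1:10) {
    s <- dna(paste(sample(c("A", "C", "G", "T"), 24, replace = TRUE), collapse = ""))
    expect_equal(melting_temperature(s), melting_temperature(revcomp(s)),
                 tolerance = 1e-10)
    # replacing a terminal A/T base pair by G/C stabilizes the duplex
    body <- substr(unclass(s), 2L, 24L)
    expect_gt(melting_temperature(dna(paste0("G", body))),
              melting_temperature(dna(paste0("A", body))))
  }
  expect_error(melting_temperature(dna("ACGT")), "6-60")
  expect_error(melting_temperature(dna(strrep("A", 61))), "6-60")
  expect_error(tm_params(na_mM = 0), "> 0")
})

test_that("minimum codon changes finds all minimal substitution paths", {
  # Asp -> Ser needs a double change by either GA->AG or GA->TC
  res <- min_codon_changes(dna("GAC"), "S")
  expect_equal(res$min_changes, 2L)
  expect_setequal(res$paths$pattern, c("GA->AG", "GA->TC"))
  expect_setequal(res$paths$codon, c("AGC", "TCC"))
  expect_equal(min_codon_changes(dna("GAC"), "D")$min_changes, 0L)
  resN <- min_codon_changes(dna("GAC"), "N")
  expect_equal(resN$min_changes, 1L)
  expect_equal(resN$paths$codon, "AAC")
  expect_error(min_codon_changes(dna("GAC"), "B"), "invalid amino-acid")
})

test_that("every sense codon is zero changes from its own amino acid (brute force)", {
  # independent oracle: enumerate the code via Biostrings GENETIC_CODE
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (cd in sense) {
    expect_equal(min_codon_changes(dna(cd), gc[[cd]])$min_changes, 0L)
  }
})
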