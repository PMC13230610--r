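test_that("explicit-flank mutagenic primers reproduce the published single examples", {
  u <- d108_unit()
  tr <- resolve_target_region(u, 108)
  p <- design_mutagenic_primer(u, tr, "AAC", label = "D108N", flanks = c(19, 19))
  expect_equal(primer_display(p), "ggttacgccgaacatgatcAACtatttcggacggccgtatg")
  u2 <- l560_unit()
  tr2 <- resolve_target_region(u2, 560)
  p2 <- design_mutagenic_primer(u2, tr2, "GAG", label = "L560E", flanks = c(21, 30))
  expect_equal(tolower(unclass(p2$sequence)),
               "ggttacccaggcctgcaaaaagagtacaatttcaaattcaagcacaccaaaagc")
})

test_that("a wild-type payload yields a primer identical to the template slice", {
  u <- d108_unit()
  tr <- resolve_target_region(u, 108)
  p <- design_mutagenic_primer(u, tr, "GAC", label = "D108D", flanks = c(19, 19))
  slice <- substr(unclass(u$sequence), tr$span[1] - 19 + 1, tr$span[2] + 19)
  expect_equal(unclass(p$sequence), slice)
})

test_that("saturation arrays share flanks and differ only in the payload codon", {
  u <- d108_unit()
  tr <- resolve_target_region(u, 108)
  arr <- design_saturation_array(u, tr, flanks = c(19, 19))
  expect_length(arr, 20L)
  expect_equal(names(arr), sort(names(arr)))
  seqs <- vapply(arr, function(p) unclass(p$sequence), "")
  expect_length(unique(substr(seqs, 1, 19)), 1L)
  expect_length(unique(substr(seqs, 23, 41)), 1L)
  payloads <- vapply(arr, function(p) unclass(p$payload), "")
  expect_equal(unname(payloads), unname(midas_codon_table()$codons))
  # single-member array: identity only
  arr1 <- design_saturation_array(u, tr, aa_set = "D", flanks = c(19, 19))
  expect_length(arr1, 1L)
  expect_equal(unclass(arr1$D108D$payload), "GAC")
})

test_that("the counter primer's reverse complement prefixes every sibling mutagenic primer", {
  u <- d108_unit()
  tr <- resolve_target_region(u, 108)
  arr <- design_saturation_array(u, tr, flanks = c(19, 19))
  ctr <- design_counter_primer(u, tr, arr[[1]], length = 19)
  expect_equal(ctr$role, "R_counter")
  pref <- unclass(revcomp(ctr$sequence))
  for (p in arr) expect_true(startsWith(unclass(p$sequence), pref))
})

test_that("reverse-mutagenic mode is mirror-symmetric with a forward counter", {
  u <- d108_unit()
  tr <- resolve_target_region(u, 108)
  p <- design_mutagenic_primer(u, tr, "AAC", label = "D108N",
                               orientation = "reverse", flanks = c(19, 19))
  expect_equal(p$role, "R_mut")
  # reverse primer = revcomp(upstream flank + payload + downstream flank)
  fwd_equiv <- design_mutagenic_primer(u, tr, "AAC", flanks = c(19, 19))
  expect_equal(unclass(p$sequence), unclass(revcomp(fwd_equiv$sequence)))
  ctr <- design_counter_primer(u, tr, p, length = 19)
  expect_equal(ctr$role, "F_counter")
  # the counter anneals just downstream of the TR, overlapping the 5'
  # region of the reverse-mutagenic primer
  expect_true(endsWith(unclass(revcomp(p$sequence)), unclass(ctr$sequence)))
})

test_that("auto-length flanks stay in 18-24 nt unless the Tm extension flag is set", {
  u <- d108_unit()
  set.seed(21)
  residues <- sample(30:280, 8)
  for (r in residues) {
    tr <- resolve_target_region(u, r)
    p <- tryCatch(suppressWarnings(design_mutagenic_primer(u, tr, "GCC", label = "x")),
                  error = identity)
    if (inherits(p, "error")) {
      # an AT-rich context can make the window unreachable; the failure
      # must be diagnosed, not silent
      expect_match(conditionMessage(p), "unreachable")
    } else {
      ok <- all(p$flanks >= 18L & p$flanks <= 24L)
      expect_true(ok || p$tm_extended)
      if (!p$tm_extended) expect_gte(p$overlap_tm, 60)
    }
  }
})

test_that("tag validation finds planted collisions and passes the packaged tag", {
  u <- d108_unit()
  rep <- validate_tag(fx$tag, u)
  expect_true(rep$pass)
  # a 23-nt slice of the template must fail with a full-length match
  slice <- dna(substr(unclass(u$sequence), 101, 123))
  rep2 <- validate_tag(slice, u)
  expect_false(rep2$pass)
  expect_equal(rep2$longest_match, 23L)
  # stringency 0 is unsatisfiable: some short substring is always shared
  rep3 <- validate_tag(fx$tag, u, stringency = 0L)
  expect_false(rep3$pass)
  expect_error(validate_tag(dna("ACGTACGTACGT"), u), ">= 15")
})

test_that("generated tags are deterministic and free of >= 12 nt template matches", {
  u <- d108_unit()
  t1 <- generate_tag(u, seed = 4)
  t2 <- generate_tag(u, seed = 4)
  expect_identical(unclass(t1), unclass(t2))
  # independent exhaustive scan at k = 12 on both strands
  tg <- unclass(t1)
  templ <- unclass(u$sequence)
  templ_rc <- unclass(revcomp(u$sequence))
  kmers <- substring(tg, 1:(nchar(tg) - 11), 12:nchar(tg))
  hits <- vapply(kmers, function(k) grepl(k, templ, fixed = TRUE) ||
                   grepl(k, templ_rc, fixed = TRUE), logical(1))
  expect_false(any(hits))
})

test_that("outer primers carry tags only in monotemplated mode", {
  u <- d108_unit()
  poly <- suppressWarnings(design_outer_primers(u, mode = "polytemplated"))
  expect_named(poly, c("Fo", "Ro"))
  expect_null(poly$Fo$tag)
  mono <- suppressWarnings(design_outer_primers(u, mode = "monotemplated",
                                                 tags = list(fo = fx$tag), seed = 3))
  expect_true(startsWith(tolower(unclass(mono$Fo$sequence)),
                         "agttctgggggcagctctagagc"))
  expect_true(all(c("Fo'", "Ro'") %in% names(mono)))
  # nested primers default to exactly the tag sequence
  expect_identical(unclass(mono[["Fo'"]]$sequence), toupper(unclass(fx$tag)))
  # a template-colliding tag is rejected
  slice <- substr(unclass(u$sequence), 101, 123)
  expect_error(suppressWarnings(design_outer_primers(u, mode = "monotemplated",
                                                      tags = list(fo = slice))), "shares")
})
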