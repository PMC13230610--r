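two_tr_sets <- function(unit, aa1 = c("A", "C", "D", "E", "F", "G"),
                        aa2 = c("K", "L", "M", "N", "P", "Q"),
                        r1 = 60, r2 = 200) {
  list(saturation_set(resolve_target_region(unit, r1), aa1),
       saturation_set(resolve_target_region(unit, r2), aa2))
}

synth_unit <- function() cached("asm_unit", synthetic_unit(seed = 3, cds_length = 900,
                                                           name = "synth"))

test_that("variant enumeration is the ordered cross product of the sets", {
  u <- synth_unit()
  sets <- two_tr_sets(u)
  v <- enumerate_variants(sets)
  expect_equal(attr(v, "count"), 36L)
  expect_equal(nrow(v), 36L)
  # rightmost TR varies fastest; labels join per-TR labels
  expect_equal(v$label[1:2], c("T60A+T200K", "T60A+T200L"))
  expect_equal(anyDuplicated(v$label), 0L)
  v20 <- enumerate_variants(list(saturation_set(resolve_target_region(u, 60)),
                                 saturation_set(resolve_target_region(u, 200))))
  expect_equal(attr(v20, "count"), 400L)
  v0 <- enumerate_variants(list())
  expect_equal(attr(v0, "count"), 1L)
  expect_equal(v0$label, "parent")
})

test_that("per-segment plans have i+1 segments and cross-product secondaries", {
  u <- synth_unit()
  plan <- suppressWarnings(plan_assembly(u, two_tr_sets(u), scheme = "per-segment"))
  expect_equal(max(plan$primary$segment), 3L)
  expect_equal(plan$counts$n_primary_mutagenic, 12L)
  expect_equal(plan$counts$n_primary_constant, 1L)
  expect_equal(plan$counts$n_secondary, 36L)
  # 1 TR, 1 variant degenerates to the two-segment monofocal layout
  one <- suppressWarnings(plan_assembly(
    u, list(saturation_set(resolve_target_region(u, 60), "A"))))
  expect_equal(max(one$primary$segment), 2L)
  expect_equal(one$counts$n_secondary, 1L)
})

test_that("per-permutation plans run one mutagenic primary per permutation", {
  u <- synth_unit()
  sets20 <- list(saturation_set(resolve_target_region(u, 60)),
                 saturation_set(resolve_target_region(u, 200)))
  plan <- suppressWarnings(plan_assembly(u, sets20, scheme = "per-permutation"))
  expect_equal(plan$counts$n_primary_mutagenic, 400L)
  expect_equal(plan$counts$n_secondary, 400L)
  # each secondary consumes exactly its own permutation's middle amplicon
  expect_equal(anyDuplicated(plan$secondary$amplicons), 0L)
})

test_that("TRs within reach of one oligo are merged; wide close pairs are rejected", {
  u <- synth_unit()
  s1 <- saturation_set(resolve_target_region(u, 100), c("A", "C"))
  s2 <- saturation_set(resolve_target_region(u, 102), c("D", "E"))
  plan <- suppressWarnings(plan_assembly(u, list(s1, s2)))
  expect_equal(plan$counts$n_tr, 1L)
  expect_equal(plan$counts$n_secondary, 4L)
  expect_equal(max(plan$primary$segment), 2L)
  s3 <- saturation_set(resolve_target_region(u, 110), c("A", "C"))
  expect_error(suppressWarnings(plan_assembly(u, list(s1, s3))),
               "combined span")
  expect_error(suppressWarnings(plan_assembly(u, list(s2, s1))), "ordered")
})

test_that("simulated secondaries equal the payload-edited template window", {
  u <- synth_unit()
  plan <- suppressWarnings(plan_assembly(u, two_tr_sets(u)))
  v <- enumerate_variants(plan$sets)
  for (lab in v$label[c(1, 17, 36)]) {
    prods <- simulate_assembly(plan, lab)
    expect_length(prods, 1L)
    expect_identical(prods, unclass(expected_product(plan, lab)))
  }
})

test_that("indel payloads shift product length by exactly the net indel", {
  u <- synth_unit()
  tr <- resolve_target_region(u, 150)
  ss <- substitution_set(tr, list(
    ins2 = paste0("GGAGGC", unclass(tr$wt_codons)),   # insert two codons
    del = "",                                          # delete the codon
    same = "GCC"))
  plan <- suppressWarnings(plan_assembly(u, list(ss)))
  parent_len <- {
    fo <- plan$primers[[plan$outer[["Fo"]]]]; ro <- plan$primers[[plan$outer[["Ro"]]]]
    ro$anneal_span[2] - fo$anneal_span[1]
  }
  expect_equal(nchar(simulate_assembly(plan, "ins2")), parent_len + 6L)
  expect_equal(nchar(simulate_assembly(plan, "del")), parent_len - 3L)
  expect_equal(nchar(simulate_assembly(plan, "same")), parent_len)
})

test_that("untagged secondaries re-amplify residual plasmid; tagged ones cannot", {
  u <- synth_unit()
  sets <- two_tr_sets(u, aa1 = c("A", "S"), aa2 = c("K", "L"))
  pm <- suppressWarnings(plan_assembly(u, sets, mode = "polytemplated"))
  lab <- pm$secondary$variant[1]
  mixed <- simulate_assembly(pm, lab, residual_template = TRUE)
  expect_length(mixed, 2L)   # mutant + parental
  mm <- suppressWarnings(plan_assembly(u, sets, mode = "monotemplated",
                                       tags = list(fo = fx$tag), seed = 7))
  clean <- simulate_assembly(mm, lab, residual_template = TRUE)
  expect_length(clean, 1L)
  expect_identical(clean, unclass(expected_product(mm, lab)))
  # nested primers alone yield nothing from the raw plasmid
  fo_n <- mm$primers[[mm$outer[["Fo'"]]]]
  ro_n <- mm$primers[[mm$outer[["Ro'"]]]]
  expect_length(simulate_pcr(u, fo_n, ro_n), 0L)
})

test_that("per-segment and per-permutation schemes produce identical product sets", {
  u <- synth_unit()
  sets <- two_tr_sets(u, aa1 = c("A", "C", "D"), aa2 = c("K", "L", "M"))
  pa <- suppressWarnings(plan_assembly(u, sets, scheme = "per-segment"))
  pb <- suppressWarnings(plan_assembly(u, sets, scheme = "per-permutation"))
  v <- enumerate_variants(sets)
  prods_a <- sort(vapply(v$label, function(l) simulate_assembly(pa, l)[1], ""))
  prods_b <- sort(vapply(v$label, function(l) simulate_assembly(pb, l)[1], ""))
  expect_identical(unname(prods_a), unname(prods_b))
})

test_that("plate layout fills row-major without double-assigning wells", {
  l36 <- layout_plates(sprintf("v%02d", 1:36))
  expect_equal(l36$well[1], "A1")
  expect_equal(l36$well[36], "C12")
  expect_equal(anyDuplicated(paste(l36$plate, l36$well)), 0L)
  l400 <- layout_plates(sprintf("v%03d", 1:400))
  expect_equal(max(l400$plate), 5L)
  expect_equal(sum(l400$plate == 5L), 16L)
  l384 <- layout_plates(sprintf("v%03d", 1:400), plate_size = 384L)
  expect_equal(max(l384$plate), 2L)
  expect_equal(l384$well[384], "P24")
  l0 <- layout_plates(character(0))
  expect_equal(nrow(l0), 0L)
  ctl <- layout_plates(sprintf("v%d", 1:4), controls = c("parent", "no-template"))
  expect_equal(ctl$label[5:6], c("parent", "no-template"))
})
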