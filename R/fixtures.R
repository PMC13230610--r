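#' Packaged reference primer arrays and tags
#'
#' Published saturation-mutagenesis primer arrays for two single-codon
#' target regions (NanoLuc D108 and an indicator-fusion L560), their shared
#' counter primers, the outer primer pair, the monotemplated 5' tag, linker
#' length/composition series, and a C-terminal peptide (SmBiT) variant
#' series — all stored verbatim as printed, with local template fragments
#' reconstructed from their non-mutagenic portions.
#'
#' The printed D108W forward primer omits one template base relative to its
#' 19 sibling primers (a one-base typo in its 3' arm); both the verbatim
#' string and the flank-consistent regularized form are stored, with the
#' regularized form used as the reference in regeneration checks.
#'
#' @return Nested list of fixtures; see the source for fields.
#' @export
midas_fixtures <- function() {
  tab <- midas_codon_table()
  d108_f5 <- "ggttacgccgaacatgatc"
  d108_f3 <- "tatttcggacggccgtatg"
  l560_f5 <- "ggttacccaggcctgcaaaaa"
  l560_f3 <- "tacaatttcaaattcaagcacaccaaaagc"
  mk_array <- function(f5, f3, gene, wt, residue) {
    seqs <- paste0(f5, tolower(tab$codons), f3)
    names(seqs) <- paste0(gene, "-", wt, residue, names(tab$codons), "-F")
    seqs
  }
  d108 <- mk_array(d108_f5, d108_f3, "NanoLuc", "D", 108)
  d108_verbatim <- d108
  # as printed: W primer lacks the first base of the 3' arm
  d108_verbatim["NanoLuc-D108W-F"] <- paste0(d108_f5, "tgg", sub("^t", "", d108_f3))
  l560 <- mk_array(l560_f5, l560_f3, "ACh NeuBI", "L", 560)
  list(
    codon_table = tab,
    tag = dna("agttctgggggcagctctagagc"),
    outer = c("MIDAS-CMV-F" = "ggccagatatacgcgttgacattg",
              "MIDAS-BGH-R" = "ctttccgcctcagaagccatagag"),
    d108 = list(
      gene = "NanoLuc", residue = 108L, wt_aa = "D",
      flank5 = d108_f5, wt_codon = "gac", flank3 = d108_f3,
      local_template = paste0(d108_f5, "gac", d108_f3),
      counter = c("NanoLuc-D108-R" = "gatcatgttcggcgtaacc"),
      array = d108, array_verbatim = d108_verbatim,
      w_regularized = TRUE),
    l560 = list(
      gene = "ACh NeuBI", residue = 560L, wt_aa = "L",
      flank5 = l560_f5, wt_codon = "ctg", flank3 = l560_f3,
      local_template = paste0(l560_f5, "ctg", l560_f3),
      counter = c("ACh NeuBI-L560-R" = "tttttgcaggcctgggtaacc"),
      array = l560, array_verbatim = l560,
      w_regularized = FALSE),
    linker1_length = c(
      "before linker1_R" = "cgggaaccccagaatatccacaag",
      "linker1_0aa_F" = "cttgtggatattctggggttcccg",
      "linker1_1aa_F" = "cttgtggatattctggggttcccgGGTGTGACCGGCTACCGGCTG",
      "linker1_2aa_F" = "cttgtggatattctggggttcccgGGTggaGTGACCGGCTACCGGCTG",
      "linker1_3aa_F" = "cttgtggatattctggggttcccgGGTggagggGTGACCGGCTACCGGCTG",
      "linker1_4aa_F" = "cttgtggatattctggggttcccgGGTggagggGGAGTGACCGGCTACCGGCTG",
      "linker1_5aa_F" = "cttgtggatattctggggttcccgGGTggagggGGAggtGTGACCGGCTACCGGCTG"),
    linker2_length = c(
      "before linker2_R" = "GCTGTTGATGGTTACTCGGAACAG",
      "linker2_0aa_F" = "CTGTTCCGAGTAACCATCAACAGCgcgactactgatccagaaggtgc",
      "linker2_1aa_F" = "CTGTTCCGAGTAACCATCAACAGCggagcgactactgatccagaaggtgc",
      "linker2_2aa_F" = "CTGTTCCGAGTAACCATCAACAGCggaGGCgcgactactgatccagaaggtgc",
      "linker2_3aa_F" = "CTGTTCCGAGTAACCATCAACAGCggaGGCggagcgactactgatccagaaggtgc",
      "linker2_4aa_F" = "CTGTTCCGAGTAACCATCAACAGCggaGGCggaggtgcgactactgatccagaaggtgc",
      "linker2_5aa_F" = "CTGTTCCGAGTAACCATCAACAGCggaGGCggaggtggagcgactactgatccagaaggtgc"),
    linker1_composition = c(
      A = "cttgtggatattctggggttcccgGCTGTGACCGGCTACCGGCTG",
      R = "cttgtggatattctggggttcccgCGTGTGACCGGCTACCGGCTG",
      N = "cttgtggatattctggggttcccgAACGTGACCGGCTACCGGCTG",
      D = "cttgtggatattctggggttcccgGACGTGACCGGCTACCGGCTG",
      C = "cttgtggatattctggggttcccgTGCGTGACCGGCTACCGGCTG",
      E = "cttgtggatattctggggttcccgGAAGTGACCGGCTACCGGCTG",
      Q = "cttgtggatattctggggttcccgCAAGTGACCGGCTACCGGCTG",
      H = "cttgtggatattctggggttcccgCATGTGACCGGCTACCGGCTG",
      I = "cttgtggatattctggggttcccgATCGTGACCGGCTACCGGCTG",
      L = "cttgtggatattctggggttcccgCTCGTGACCGGCTACCGGCTG",
      K = "cttgtggatattctggggttcccgAAAGTGACCGGCTACCGGCTG",
      M = "cttgtggatattctggggttcccgATGGTGACCGGCTACCGGCTG",
      F = "cttgtggatattctggggttcccgTTCGTGACCGGCTACCGGCTG",
      P = "cttgtggatattctggggttcccgCCTGTGACCGGCTACCGGCTG",
      S = "cttgtggatattctggggttcccgTCCGTGACCGGCTACCGGCTG",
      T = "cttgtggatattctggggttcccgACCGTGACCGGCTACCGGCTG",
      W = "cttgtggatattctggggttcccgTGGGTGACCGGCTACCGGCTG",
      Y = "cttgtggatattctggggttcccgTACGTGACCGGCTACCGGCTG",
      V = "cttgtggatattctggggttcccgGTAGTGACCGGCTACCGGCTG"),
    smbit_series = c(
      "after SmBiT_F" = "GGCGGAAGTGGAGGTAGCTTC",
      "SmBiT(-C1)_R" = "GAAGCTACCTCCACTTCCGCCAATCTCCTCGAACAGCCGGTAG",
      "SmBiT(-C2)_R" = "GAAGCTACCTCCACTTCCGCCCTCCTCGAACAGCCGGTAGC",
      "SmBiT(-C3)_R" = "GAAGCTACCTCCACTTCCGCCCTCGAACAGCCGGTAGCCG",
      "SmBiT(L163E)_R" = "GAAGCTACCTCCACTTCCGCCCAGAATCTCCTCGAATTCCCGGTAGCCGGTCACGAAc",
      "SmBiT(F164H)_R" = "GAAGCTACCTCCACTTCCGCCCAGAATCTCCTCGTGCAGCCGGTAGCCGGTCAC",
      "SmBiT(F164S)_R" = "GAAGCTACCTCCACTTCCGCCCAGAATCTCCTCGCTCAGCCGGTAGCCGGTCAC",
      "SmBiT(L163E,-C3)_R" = "GAAGCTACCTCCACTTCCGCCCTCGAATTCCCGGTAGCCGGTCACGAAc",
      "SmBiT(F164H,-C3)_R" = "GAAGCTACCTCCACTTCCGCCCTCGTGCAGCCGGTAGCCGGTCAC",
      "SmBiT(F164S,-C3)_R" = "GAAGCTACCTCCACTTCCGCCCTCGCTCAGCCGGTAGCCGGTCAC")
  )
}

# seeded random DNA of length n
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Generate a seeded synthetic transcription unit
#'
#' Deterministic random template with promoter/CDS/polyA annotations. The
#' CDS starts with ATG, ends with a stop codon, and contains no internal
#' in-frame stop. Local sequence fragments (e.g. the packaged primer-array
#' templates) can be embedded so that a given fixture residue lands at its
#' published position. The template is rejection-sampled to avoid sharing
#' any 12-nt run with the packaged monotemplated tag, so tag-uniqueness
#' checks are meaningful.
#'
#' @param seed Integer seed.
#' @param cds_length CDS length in nt (multiple of 3, including start and
#'   stop codons).
#' @param embed Optional list of `list(fragment=, at_residue=, flank5=)`:
#'   `fragment` is placed so its wild-type codon (starting `flank5` nt in)
#'   becomes codon `at_residue` of the CDS.
#' @param promoter_nt,polya_nt,utr_nt Lengths of the flanking features and
#'   the untranslated spacers.
#' @param name Template name.
#' @return A [transcription_unit()].
#' @export
synthetic_unit <- function(seed = 1L, cds_length = 900L, embed = list(),
                           promoter_nt = 200L, polya_nt = 150L, utr_nt = 30L,
                           name = "synth") {
  if (cds_length %% 3L != 0L) stop("cds_length must be divisible by 3", call. = FALSE)
  tag <- midas_fixtures()$tag
  for (attempt in 0:49) {
    set.seed(seed + attempt * 10000L)
    n_codons <- cds_length %/% 3L
    sense <- setdiff(names(codon_map())[codon_map() != "*"], character(0))
    body <- sample(sense, n_codons - 2L, replace = TRUE)
    cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
    for (e in embed) {
      frag <- toupper(unclass(as_dna(e$fragment)))
      at <- 3L * (e$at_residue - 1L) - e$flank5   # 0-based CDS offset
      if (at < 3L || at + nchar(frag) > cds_length - 3L) {
        stop("embedded fragment does not fit inside the CDS", call. = FALSE)
      }
      substr(cds, at + 1L, at + nchar(frag)) <- frag
    }
    aa <- translate_dna(dna(cds))
    if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))) next   # internal stop
    seqn <- paste0(rand_dna(promoter_nt), rand_dna(utr_nt), cds,
                   rand_dna(utr_nt), rand_dna(polya_nt))
    unit <- transcription_unit(
      dna(seqn),
      promoter = c(0L, promoter_nt),
      cds = c(promoter_nt + utr_nt, promoter_nt + utr_nt + cds_length),
      polya = c(nchar(seqn) - polya_nt, nchar(seqn)),
      name = name)
    if (!validate_tag(tag, unit)$pass) next   # template contains tag run
    return(unit)
  }
  stop("could not generate a clean synthetic unit", call. = FALSE)
}

#' Synthetic template carrying a packaged primer-array fragment
#'
#' Convenience wrapper around [synthetic_unit()] embedding the D108 or
#' L560 local template so the packaged arrays can be regenerated from a
#' full transcription unit.
#'
#' @param which `"d108"` or `"l560"`.
#' @param seed Seed passed through.
#' @return A [transcription_unit()].
#' @export
fixture_unit <- function(which = c("d108", "l560"), seed = 1L) {
  which <- match.arg(which)
  fx <- midas_fixtures()[[which]]
  cds_length <- if (which == "d108") 900L else 1800L
  synthetic_unit(seed = seed, cds_length = cds_length,
                 embed = list(list(fragment = fx$local_template,
                                   at_residue = fx$residue,
                                   flank5 = nchar(fx$flank5))),
                 name = fx$gene)
}

#' Planted ground truth for a synthetic multiwell screen
#'
#' Defines per-variant true activities on each substrate with planted
#' structure for recovery tests: one fully tolerant site (all substitutions
#' near wild-type activity), one intolerant site (all near zero), optional
#' substrate-preferring variants, and optional censorable variants (below
#' the specificity censoring threshold on one substrate). Transfection
#' efficiency varies per well and measurement noise is lognormal with a
#' fixed coefficient of variation.
#'
#' @param seed Integer seed.
#' @param sites Site labels; the first is planted tolerant, the second
#'   intolerant.
#' @param substitutions Substitution labels (default the 20 amino acids).
#' @param substrates Substrate (condition) names.
#' @param prefer Named character vector `"site:substitution" -> substrate`:
#'   those variants get 1.5x activity on the named substrate and 0.9x on
#'   the others.
#' @param censorable Character vector of `"site:substitution"` variants
#'   planted at 0.2x parent on the first substrate.
#' @param cv Lognormal measurement coefficient of variation (0 = noiseless).
#' @param replicates Technical replicates per well.
#' @return A `screen_truth` list.
#' @export
synthetic_screen_truth <- function(seed = 1L, sites = paste0("site", 1:4),
                                   substitutions = AA20,
                                   substrates = "S1",
                                   prefer = character(0),
                                   censorable = character(0),
                                   cv = 0.05, replicates = 3L) {
  set.seed(seed)
  ns <- length(sites); na <- length(substitutions); nb <- length(substrates)
  base <- matrix(stats::runif(ns * na, 0.3, 0.9), ns, na,
                 dimnames = list(sites, substitutions))
  base[1, ] <- stats::runif(na, 0.85, 1.15)    # tolerant site
  if (ns >= 2L) base[2, ] <- stats::runif(na, 0, 0.03)  # intolerant site
  activity <- array(rep(base, nb), dim = c(ns, na, nb),
                    dimnames = list(sites, substitutions, substrates))
  for (v in names(prefer)) {
    parts <- strsplit(v, ":", fixed = TRUE)[[1]]
    fav <- prefer[[v]]
    activity[parts[1], parts[2], ] <- 0.9 * base[parts[1], parts[2]]
    activity[parts[1], parts[2], fav] <- 1.5 * base[parts[1], parts[2]]
  }
  for (v in censorable) {
    parts <- strsplit(v, ":", fixed = TRUE)[[1]]
    activity[parts[1], parts[2], 1] <- 0.2
  }
  structure(list(seed = seed, activity = activity,
                 substrate_scale = stats::setNames(
                   stats::runif(nb, 0.5, 2), substrates),
                 reference_level = 1000,
                 cv = cv, replicates = as.integer(replicates),
                 tolerant = sites[1],
                 intolerant = if (ns >= 2L) sites[2] else NA_character_,
                 prefer = prefer, censorable = censorable),
            class = "screen_truth")
}

#' Simulate a tidy multiwell screen from planted truth
#'
#' Emits one row per variant x substrate x replicate (plus parent wells):
#' signal = true activity x substrate scale x per-well transfection
#' multiplier x lognormal noise; the reference signal shares the same
#' transfection multiplier, so expression normalization cancels it.
#' Wells are assigned by deterministic row-major plate fill.
#'
#' @param truth A [synthetic_screen_truth()].
#' @param plate_size 96 or 384.
#' @return data.frame: `plate`, `well`, `variant`, `site`, `substitution`,
#'   `condition`, `signal`, `reference_signal`.
#' @export
simulate_screen <- function(truth, plate_size = 96L) {
  stopifnot(inherits(truth, "screen_truth"))
  set.seed(truth$seed + 1L)
  dn <- dimnames(truth$activity)
  grid <- expand.grid(site = dn[[1]], substitution = dn[[2]],
                      stringsAsFactors = FALSE)
  labels <- c(paste0(grid$site, ":", grid$substitution), "parent")
  layout <- layout_plates(labels, plate_size = plate_size)
  lognoise <- function(n) {
    if (truth$cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + truth$cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  rows <- list()
  for (b in dn[[3]]) {
    for (i in seq_len(nrow(layout))) {
      lab <- layout$label[i]
      if (lab == "parent") {
        site <- NA_character_; subst <- "WT"; act <- 1
      } else {
        parts <- strsplit(lab, ":", fixed = TRUE)[[1]]
        site <- parts[1]; subst <- parts[2]
        act <- truth$activity[site, subst, b]
      }
      transfection <- stats::runif(1, 0.5, 2)
      r <- truth$replicates
      rows[[length(rows) + 1L]] <- data.frame(
        plate = layout$plate[i], well = layout$well[i], variant = lab,
        site = site, substitution = subst, condition = b,
        signal = act * truth$substrate_scale[[b]] * transfection *
          truth$reference_level * lognoise(r),
        reference_signal = truth$reference_level * transfection * lognoise(r),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate 4PL dose-response measurements
#'
#' @param doses Dose vector.
#' @param bottom,top,ec50,hill True curve parameters.
#' @param cv Lognormal noise CV (0 = noiseless).
#' @param replicates Replicates per dose.
#' @param seed Seed.
#' @return data.frame `dose`, `response`.
#' @export
simulate_dose_response <- function(doses, bottom = 1, top = 7.4, ec50 = 898,
                                   hill = 1, cv = 0, replicates = 1L,
                                   seed = 1L) {
  set.seed(seed)
  d <- rep(doses, each = replicates)
  mu <- bottom + (top - bottom) / (1 + 10^((log10(ec50) - log10(d)) * hill))
  noise <- if (cv == 0) 1 else {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(length(d), -sdlog^2 / 2, sdlog)
  }
  data.frame(dose = d, response = mu * noise)
}
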