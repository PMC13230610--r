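#' Enumerate combinatorial variants
#'
#' Cross product of per-TR substitution sets in deterministic order: TRs
#' left to right, payloads in declared order, with the rightmost TR varying
#' fastest. An empty list yields the single parent combination.
#'
#' @param substitution_sets List of [substitution_set()] ordered by
#'   template position.
#' @return data.frame with one row per variant: `label` (per-TR labels
#'   joined with `+`) and one `tr<i>` column per set; attribute `count`.
#' @export
enumerate_variants <- function(substitution_sets) {
  if (length(substitution_sets) == 0L) {
    out <- data.frame(label = "parent", stringsAsFactors = FALSE)
    attr(out, "count") <- 1L
    return(out)
  }
  labs <- lapply(substitution_sets, function(ss) names(ss$payloads))
  grid <- rev(expand.grid(rev(labs), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE))
  names(grid) <- paste0("tr", seq_along(labs))
  out <- data.frame(label = do.call(paste, c(grid, sep = "+")), grid,
                    stringsAsFactors = FALSE)
  attr(out, "count") <- nrow(out)
  out
}

# maximal suffix(a)/prefix(b) exact overlap, length >= min_overlap
find_overlap <- function(a, b, min_overlap = 18L) {
  a <- unclass(a); b <- unclass(b)
  mx <- min(nchar(a), nchar(b))
  for (k in mx:min_overlap) {
    if (substr(a, nchar(a) - k + 1L, nchar(a)) == substr(b, 1L, k)) return(k)
  }
  0L
}

#' In-silico PCR of one primer pair on one template
#'
#' A primer primes wherever its 3'-terminal `k` bases match the template
#' exactly (forward primer on the plus strand, reverse primer on the minus
#' strand); 5' portions that do not match (payloads, tags) are carried into
#' the product. All distinct products from all compatible site pairs are
#' returned; multi-site priming is therefore reported, never silently
#' resolved.
#'
#' @param template Template [dna()] sequence.
#' @param fwd,rev Forward/reverse [primer_spec()] (or plain sequences).
#' @param k 3'-terminal exact-match length required for priming.
#' @return Character vector of distinct product sequences (possibly empty).
#' @export
simulate_pcr <- function(template, fwd, rev, k = 15L) {
  template <- unclass(as_dna(if (inherits(template, "transcription_unit")) template$sequence else template))
  fseq <- unclass(if (inherits(fwd, "primer_spec")) fwd$sequence else as_dna(fwd))
  rseq <- unclass(if (inherits(rev, "primer_spec")) rev$sequence else as_dna(rev))
  if (nchar(fseq) < k || nchar(rseq) < k) stop("primer shorter than k", call. = FALSE)
  f3 <- substr(fseq, nchar(fseq) - k + 1L, nchar(fseq))
  r3rc <- unclass(revcomp(dna(substr(rseq, nchar(rseq) - k + 1L, nchar(rseq)))))
  all_pos <- function(pat) {
    m <- gregexpr(pat, template, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  fpos <- all_pos(f3)       # 1-based start of fwd 3' k-mer on plus strand
  rpos <- all_pos(r3rc)     # 1-based start of rev 3' k-mer (as plus-strand rc)
  products <- character(0)
  for (fp in fpos) {
    f_end <- fp + k - 1L    # last template base covered by fwd 3' end
    for (rp in rpos) {
      if (rp <= f_end - k + 1L) next   # reverse site must lie downstream
      mid <- if (rp > f_end + 1L) substr(template, f_end + 1L, rp - 1L) else ""
      products <- c(products, paste0(fseq, mid, unclass(revcomp(dna(rseq)))))
    }
  }
  unique(products)
}

#' Join amplicons by overlap extension
#'
#' Left-to-right assembly requiring a unique maximal exact suffix/prefix
#' overlap of at least `min_overlap` nt between adjacent amplicons.
#'
#' @param amplicons Character vector or list of amplicon sequences in
#'   template order.
#' @param min_overlap Minimum exact overlap, nt.
#' @return Assembled [dna()] sequence.
#' @export
join_amplicons <- function(amplicons, min_overlap = 18L) {
  amplicons <- vapply(amplicons, function(x) unclass(as_dna(x)), "")
  full <- amplicons[1]
  for (nxt in amplicons[-1]) {
    k <- find_overlap(full, nxt, min_overlap)
    if (k == 0L) stop("no exact overlap >= ", min_overlap,
                      " nt between adjacent amplicons", call. = FALSE)
    full <- paste0(full, substr(nxt, k + 1L, nchar(nxt)))
  }
  dna(full)
}

# merge two adjacent close TRs + their substitution sets into one
merge_close_sets <- function(unit, s1, s2, max_span_nt = 12L) {
  tr1 <- s1$tr; tr2 <- s2$tr
  span <- c(tr1$span[1], tr2$span[2])
  if (span[2] - span[1] > max_span_nt) {
    stop("TRs at residues ", tr1$first_residue, " and ", tr2$first_residue,
         " are closer than one amplicon can separate (< 60 nt apart) but ",
         "their combined span exceeds ", max_span_nt, " nt; widen the gap ",
         "or supply a single merged TR covering both", call. = FALSE)
  }
  tr <- resolve_target_region(unit, tr1$first_residue, tr2$last_residue,
                              cds_index = tr1$cds_index, max_span_nt = max_span_nt)
  gap <- substr(unclass(unit$sequence), tr1$span[2] + 1L, tr2$span[1])
  payloads <- list()
  for (l1 in names(s1$payloads)) for (l2 in names(s2$payloads)) {
    payloads[[paste0(l1, "+", l2)]] <-
      dna(paste0(s1$payloads[[l1]], gap, s2$payloads[[l2]]))
  }
  substitution_set(tr, payloads)
}

#' Plan a segmented overlap-extension assembly
#'
#' Turns ordered per-TR substitution sets into primary and secondary PCR
#' reactions under one of two combinatorial schemes. In the per-segment
#' scheme, `i` TRs give `i + 1` segments: one constant left segment and one
#' mutagenic segment per TR (the payload rides on the segment's forward
#' primer, the upstream segment's reverse counter primer supplies the
#' overlap), and secondaries are formed by the cross product of per-TR
#' amplicon choices. In the per-permutation scheme (two TRs at most), the
#' middle segment carries both payloads — TR1 on its forward primer, TR2 on
#' its mutagenic reverse primer — so there is one primary per full
#' permutation and secondaries transfer one-to-one. Monotemplated mode
#' attaches template-absent tags to the outer primers and wires the nested
#' tag primers into the secondaries.
#'
#' TRs closer than 60 nt (within reach of a single oligo) are merged into
#' one TR-carrying primer when their combined span permits.
#'
#' @param unit A [transcription_unit()].
#' @param substitution_sets List of [substitution_set()] in template order,
#'   non-overlapping.
#' @param scheme `"per-segment"` or `"per-permutation"`.
#' @param mode `"polytemplated"` or `"monotemplated"`.
#' @param tags,seed Passed to [design_outer_primers()] in monotemplated mode.
#' @param constraints A [primer_constraints()].
#' @return An `assembly_plan`: primers, `primary` and `secondary` reaction
#'   tables, and a `counts` summary.
#' @export
plan_assembly <- function(unit, substitution_sets,
                          scheme = c("per-segment", "per-permutation"),
                          mode = c("polytemplated", "monotemplated"),
                          tags = list(), seed = 1L,
                          constraints = primer_constraints()) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  sets <- substitution_sets
  if (length(sets) == 0L) stop("need at least one substitution set", call. = FALSE)
  spans <- t(vapply(sets, function(s) s$tr$span, integer(2)))
  if (is.unsorted(spans[, 1], strictly = TRUE) ||
      any(spans[-1, 1] < spans[-nrow(spans), 2])) {
    stop("TRs must be ordered and non-overlapping", call. = FALSE)
  }
  # merge TRs a single oligo can span
  i <- 1L
  while (i < length(sets)) {
    if (sets[[i + 1L]]$tr$span[1] - sets[[i]]$tr$span[2] < 60L) {
      sets[[i]] <- merge_close_sets(unit, sets[[i]], sets[[i + 1L]])
      sets[[i + 1L]] <- NULL
    } else i <- i + 1L
  }
  n_tr <- length(sets)
  edge <- min(spans[1, 1], nchar(unit$sequence) - spans[nrow(spans), 2])
  if (sets[[1]]$tr$span[1] - unit$promoter[1] < 60L ||
      unit$polya[2] - sets[[n_tr]]$tr$span[2] < 60L) {
    stop("TR too close to the template ends for outer segments", call. = FALSE)
  }
  outer <- design_outer_primers(unit, mode = mode, tags = tags, seed = seed,
                                constraints = constraints)
  sec_f <- if (mode == "monotemplated") outer[["Fo'"]] else outer$Fo
  sec_r <- if (mode == "monotemplated") outer[["Ro'"]] else outer$Ro

  primers <- list()
  for (p in outer) primers[[p$name]] <- p
  outer_names <- vapply(outer, function(p) p$name, "")
  primary <- list()
  secondary <- list()
  add_primary <- function(id, segment, variant, fwd, rev) {
    primary[[id]] <<- data.frame(
      id = id, segment = segment, variant = variant, template = unit$name,
      fwd = fwd, rev = rev, stringsAsFactors = FALSE)
  }

  if (scheme == "per-segment") {
    counters <- list()
    arrays <- list()
    for (t in seq_len(n_tr)) {
      tr <- sets[[t]]$tr
      arr <- lapply(names(sets[[t]]$payloads), function(lab) {
        design_mutagenic_primer(unit, tr, sets[[t]]$payloads[[lab]],
                                label = lab, constraints = constraints)
      })
      names(arr) <- names(sets[[t]]$payloads)
      counters[[t]] <- design_counter_primer(unit, tr, arr[[1]],
                                             constraints = constraints)
      arrays[[t]] <- arr
      primers[[counters[[t]]$name]] <- counters[[t]]
      for (p in arr) primers[[p$name]] <- p
    }
    # segment 1: Fo .. R1 (constant)
    add_primary("seg1", 1L, "constant", outer$Fo$name, counters[[1]]$name)
    # segment t+1: F_t(variant) .. R_{t+1} (or Ro for the last)
    for (t in seq_len(n_tr)) {
      rev_name <- if (t < n_tr) counters[[t + 1L]]$name else outer$Ro$name
      for (lab in names(arrays[[t]])) {
        add_primary(sprintf("seg%d:%s", t + 1L, lab), t + 1L, lab,
                    arrays[[t]][[lab]]$name, rev_name)
      }
    }
    variants <- enumerate_variants(sets)
    for (r in seq_len(nrow(variants))) {
      amps <- c("seg1", vapply(seq_len(n_tr), function(t)
        sprintf("seg%d:%s", t + 1L, variants[[paste0("tr", t)]][r]), ""))
      secondary[[variants$label[r]]] <- data.frame(
        variant = variants$label[r],
        amplicons = paste(amps, collapse = ";"),
        fwd = sec_f$name, rev = sec_r$name, stringsAsFactors = FALSE)
    }
    n_constant <- 1L
  } else {
    if (n_tr > 2L) {
      stop("per-permutation scheme supports at most two TRs", call. = FALSE)
    }
    variants <- enumerate_variants(sets)
    if (n_tr == 1L) {
      tr <- sets[[1]]$tr
      arr <- lapply(names(sets[[1]]$payloads), function(lab)
        design_mutagenic_primer(unit, tr, sets[[1]]$payloads[[lab]],
                                label = lab, constraints = constraints))
      names(arr) <- names(sets[[1]]$payloads)
      counter <- design_counter_primer(unit, tr, arr[[1]], constraints = constraints)
      primers[[counter$name]] <- counter
      for (p in arr) primers[[p$name]] <- p
      add_primary("seg1", 1L, "constant", outer$Fo$name, counter$name)
      for (lab in names(arr)) {
        add_primary(sprintf("seg2:%s", lab), 2L, lab, arr[[lab]]$name, outer$Ro$name)
      }
      for (r in seq_len(nrow(variants))) {
        secondary[[variants$label[r]]] <- data.frame(
          variant = variants$label[r],
          amplicons = paste(c("seg1", sprintf("seg2:%s", variants$tr1[r])), collapse = ";"),
          fwd = sec_f$name, rev = sec_r$name, stringsAsFactors = FALSE)
      }
      n_constant <- 1L
    } else {
      tr1 <- sets[[1]]$tr; tr2 <- sets[[2]]$tr
      f_arr <- lapply(names(sets[[1]]$payloads), function(lab)
        design_mutagenic_primer(unit, tr1, sets[[1]]$payloads[[lab]],
                                label = lab, constraints = constraints))
      names(f_arr) <- names(sets[[1]]$payloads)
      r_arr <- lapply(names(sets[[2]]$payloads), function(lab)
        design_mutagenic_primer(unit, tr2, sets[[2]]$payloads[[lab]],
                                label = lab, orientation = "reverse",
                                constraints = constraints))
      names(r_arr) <- names(sets[[2]]$payloads)
      counter1 <- design_counter_primer(unit, tr1, f_arr[[1]], constraints = constraints)
      counter2 <- design_counter_primer(unit, tr2, r_arr[[1]], constraints = constraints)
      primers[[counter1$name]] <- counter1
      primers[[counter2$name]] <- counter2
      for (p in c(f_arr, r_arr)) primers[[p$name]] <- p
      add_primary("seg1", 1L, "constant", outer$Fo$name, counter1$name)
      add_primary("seg3", 3L, "constant", counter2$name, outer$Ro$name)
      for (r in seq_len(nrow(variants))) {
        lab <- variants$label[r]
        add_primary(sprintf("seg2:%s", lab), 2L, lab,
                    f_arr[[variants$tr1[r]]]$name, r_arr[[variants$tr2[r]]]$name)
        secondary[[lab]] <- data.frame(
          variant = lab,
          amplicons = paste(c("seg1", sprintf("seg2:%s", lab), "seg3"), collapse = ";"),
          fwd = sec_f$name, rev = sec_r$name, stringsAsFactors = FALSE)
      }
      n_constant <- 2L
    }
  }
  primary <- do.call(rbind, primary)
  secondary <- do.call(rbind, secondary)
  rownames(primary) <- rownames(secondary) <- NULL
  structure(list(
    scheme = scheme, mode = mode, unit = unit, sets = sets,
    primers = primers, outer = outer_names,
    primary = primary, secondary = secondary,
    counts = list(n_tr = n_tr,
                  n_primary = nrow(primary),
                  n_primary_mutagenic = sum(primary$variant != "constant"),
                  n_primary_constant = n_constant,
                  n_secondary = nrow(secondary))),
    class = "assembly_plan")
}

#' @export
print.assembly_plan <- function(x, ...) {
  cat(sprintf("<assembly_plan %s/%s> %d TR(s); %d primary (%d mutagenic + %d constant); %d secondary\n",
              x$scheme, x$mode, x$counts$n_tr, x$counts$n_primary,
              x$counts$n_primary_mutagenic, x$counts$n_primary_constant,
              x$counts$n_secondary))
  invisible(x)
}

# amplicon sequence of one primary reaction (unique product required)
primary_amplicon <- function(plan, id, k = 15L) {
  row <- plan$primary[plan$primary$id == id, ]
  if (nrow(row) != 1L) stop("unknown primary reaction: ", id, call. = FALSE)
  prods <- simulate_pcr(plan$unit, plan$primers[[row$fwd]],
                        plan$primers[[row$rev]], k = k)
  if (length(prods) != 1L) {
    stop("primary ", id, " yields ", length(prods), " products", call. = FALSE)
  }
  dna(prods)
}

#' Simulate a planned secondary reaction
#'
#' In-silico overlap-extension PCR of one secondary reaction: the
#' contributing primary amplicons are joined by exact overlap, then the
#' secondary primer pair is applied to every template present in the mix —
#' the assembled product plus, optionally, residual plasmid template
#' carried over from unpurified mutagenic primaries. All distinct products
#' are returned, so parental re-amplification shows up as a mixed product
#' set rather than being hidden.
#'
#' @param plan An [plan_assembly()] result.
#' @param variant Variant label of the secondary reaction.
#' @param residual_template `TRUE` to include the original template in the
#'   reaction mix (models unpurified primary carry-over).
#' @param k Priming-site exact-match length.
#' @return Character vector of distinct full-length product sequences.
#' @export
simulate_assembly <- function(plan, variant, residual_template = FALSE, k = 15L) {
  row <- plan$secondary[plan$secondary$variant == variant, ]
  if (nrow(row) != 1L) stop("unknown secondary reaction: ", variant, call. = FALSE)
  ids <- strsplit(row$amplicons, ";", fixed = TRUE)[[1]]
  amps <- lapply(ids, function(id) primary_amplicon(plan, id, k = k))
  assembled <- join_amplicons(amps)
  mix <- list(assembled)
  if (residual_template) mix <- c(mix, list(plan$unit$sequence))
  fwd <- plan$primers[[row$fwd]]; rev <- plan$primers[[row$rev]]
  unique(unlist(lapply(mix, function(tmpl) simulate_pcr(tmpl, fwd, rev, k = k))))
}

#' Expected full-length variant sequence
#'
#' The product a secondary reaction should yield: the template edited at
#' every TR with the variant's payloads, windowed to the outer-primer span,
#' with 5' tags attached in monotemplated mode.
#'
#' @param plan An [plan_assembly()] result.
#' @param variant Variant label.
#' @return A [dna()] sequence.
#' @export
expected_product <- function(plan, variant) {
  variants <- enumerate_variants(plan$sets)
  r <- which(variants$label == variant)
  if (length(r) != 1L) stop("unknown variant: ", variant, call. = FALSE)
  s <- unclass(plan$unit$sequence)
  # apply payloads right-to-left so spans stay valid
  for (t in rev(seq_along(plan$sets))) {
    tr <- plan$sets[[t]]$tr
    pl <- unclass(plan$sets[[t]]$payloads[[variants[[paste0("tr", t)]][r]]])
    s <- paste0(substr(s, 1L, tr$span[1]), pl, substr(s, tr$span[2] + 1L, nchar(s)))
  }
  fo <- plan$primers[[plan$outer[["Fo"]]]]
  ro <- plan$primers[[plan$outer[["Ro"]]]]
  shift <- nchar(s) - nchar(plan$unit$sequence)   # net payload indel
  core <- substr(s, fo$anneal_span[1] + 1L, ro$anneal_span[2] + shift)
  fo_tag <- if (!is.null(fo$tag)) unclass(fo$tag) else ""
  ro_tag <- if (!is.null(ro$tag)) unclass(revcomp(ro$tag)) else ""
  dna(paste0(fo_tag, core, ro_tag))
}

#' Translate the CDS of an assembled product
#'
#' Locates the (unmutated) CDS start within a full-length product and
#' translates up to the first stop codon. Assumes the CDS begins upstream
#' of the first TR and ends with a stop codon, as the synthetic templates
#' guarantee.
#'
#' @param product Product sequence from [simulate_assembly()].
#' @param unit The source [transcription_unit()].
#' @param cds_index Which CDS to translate.
#' @return Amino-acid string without the trailing stop.
#' @export
product_cds_protein <- function(product, unit, cds_index = 1L) {
  product <- unclass(as_dna(product))
  cds <- unit$cds[[cds_index]]
  anchor <- substr(unclass(unit$sequence), cds[1] + 1L, cds[1] + 21L)
  pos <- regexpr(anchor, product, fixed = TRUE)
  if (pos == -1L) stop("CDS start not found in product", call. = FALSE)
  aa <- translate_dna(dna(substr(product, pos, nchar(product))))
  sub("\\*.*$", "", aa)
}

#' Lay out reactions on multiwell plates
#'
#' Deterministic row-major fill of 96- or 384-well plates, with optional
#' control labels appended in the trailing wells of the last plate.
#'
#' @param labels Character vector of reaction/variant labels, in fill order.
#' @param plate_size 96 or 384.
#' @param controls Optional character vector of control labels (e.g.
#'   parent, no-template) placed after the reactions.
#' @return A `plate_layout`: data.frame with `plate`, `well`, `row`,
#'   `col`, `label`.
#' @export
layout_plates <- function(labels, plate_size = 96L, controls = character(0)) {
  stopifnot(plate_size %in% c(96L, 384L))
  labels <- c(labels, controls)
  nrow_p <- if (plate_size == 96L) 8L else 16L
  ncol_p <- if (plate_size == 96L) 12L else 24L
  n <- length(labels)
  if (n == 0L) {
    out <- data.frame(plate = integer(0), well = character(0),
                      row = character(0), col = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
    class(out) <- c("plate_layout", "data.frame")
    return(out)
  }
  idx <- seq_len(n) - 1L
  plate <- idx %/% plate_size + 1L
  within <- idx %% plate_size
  row <- LETTERS[within %/% ncol_p + 1L]
  col <- within %% ncol_p + 1L
  out <- data.frame(plate = plate, well = paste0(row, col), row = row,
                    col = col, label = labels, stringsAsFactors = FALSE)
  attr(out, "plate_size") <- plate_size
  class(out) <- c("plate_layout", "data.frame")
  out
}
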