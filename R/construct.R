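#' Transcription unit
#'
#' An annotated linear expression template: promoter, one or more coding
#' sequences (supporting bicistronic layouts with an intervening element
#' such as a ribosome-skipping peptide), and a polyadenylation signal, all
#' on the forward strand. Internal coordinates are 0-based half-open;
#' user-facing residue numbers are 1-based with an optional per-CDS offset
#' so that whole-fusion residue labels can be used directly.
#'
#' @param sequence Full template [dna()] sequence.
#' @param promoter,polya Integer length-2 vectors `c(start, end)`, 0-based
#'   half-open spans on `sequence`.
#' @param cds List of spans (or a single span) for the CDS feature(s), in
#'   template order; each length must be divisible by 3.
#' @param cds_offset Integer vector, per-CDS residue-numbering offset:
#'   user residue `r` maps to codon index `r - offset` within the CDS.
#' @param name Template identifier.
#' @return A `transcription_unit`.
#' @export
transcription_unit <- function(sequence, promoter, cds, polya,
                               cds_offset = 0L, name = "template") {
  sequence <- as_dna(sequence)
  if (is.numeric(cds)) cds <- list(cds)
  spans <- c(list(promoter = promoter), stats::setNames(cds, paste0("cds", seq_along(cds))),
             list(polya = polya))
  n <- nchar(sequence)
  for (nm in names(spans)) {
    sp <- spans[[nm]]
    if (length(sp) != 2L || sp[1] < 0 || sp[2] > n || sp[1] >= sp[2]) {
      stop("feature '", nm, "' span out of bounds or empty", call. = FALSE)
    }
  }
  ord <- order(vapply(spans, `[`, 0, 1L))
  if (!identical(names(spans)[ord], names(spans))) {
    stop("features must be ordered promoter < CDS < polyA on the forward strand",
         call. = FALSE)
  }
  starts <- vapply(spans, `[`, 0, 1L); ends <- vapply(spans, `[`, 0, 2L)
  if (any(starts[-1] < ends[-length(ends)])) {
    stop("features overlap", call. = FALSE)
  }
  for (i in seq_along(cds)) {
    if ((cds[[i]][2] - cds[[i]][1]) %% 3L != 0L) {
      stop("CDS not codon-aligned: length ", cds[[i]][2] - cds[[i]][1],
           " nt is not a multiple of 3", call. = FALSE)
    }
  }
  cds_offset <- rep_len(as.integer(cds_offset), length(cds))
  structure(list(sequence = sequence, promoter = as.integer(promoter),
                 cds = lapply(cds, as.integer), polya = as.integer(polya),
                 cds_offset = cds_offset, name = name),
            class = "transcription_unit")
}

#' @export
print.transcription_unit <- function(x, ...) {
  cat(sprintf("<transcription_unit '%s'> %d nt; promoter [%d,%d); %d CDS; polyA [%d,%d)\n",
              x$name, nchar(x$sequence), x$promoter[1], x$promoter[2],
              length(x$cds), x$polya[1], x$polya[2]))
  for (i in seq_along(x$cds)) {
    cat(sprintf("  CDS %d: [%d,%d) (%d aa, residue offset %d)\n", i,
                x$cds[[i]][1], x$cds[[i]][2],
                (x$cds[[i]][2] - x$cds[[i]][1]) %/% 3L, x$cds_offset[i]))
  }
  invisible(x)
}

#' Build a transcription unit from a sequence record plus feature annotations
#'
#' Thin validated constructor used by the file readers: annotations must
#' name exactly one promoter, at least one CDS, and one polyA feature.
#'
#' @param sequence Template [dna()] sequence.
#' @param features data.frame with columns `type` (promoter/CDS/polyA),
#'   `start`, `end` (0-based half-open).
#' @param cds_offset,name Passed to [transcription_unit()].
#' @return A `transcription_unit`.
#' @export
load_unit <- function(sequence, features, cds_offset = 0L, name = "template") {
  ft <- tolower(features$type)
  if (sum(ft == "promoter") != 1L || sum(ft == "polya") != 1L || !any(ft == "cds")) {
    stop("annotations must name exactly one promoter, >= 1 CDS, one polyA; got: ",
         paste(features$type, collapse = ", "), call. = FALSE)
  }
  span <- function(i) c(features$start[i], features$end[i])
  cds_rows <- which(ft == "cds")
  cds_rows <- cds_rows[order(features$start[cds_rows])]
  transcription_unit(sequence,
                     promoter = span(which(ft == "promoter")),
                     cds = lapply(cds_rows, span),
                     polya = span(which(ft == "polya")),
                     cds_offset = cds_offset, name = name)
}

#' Resolve a target region
#'
#' Maps a user residue range to a codon-aligned nucleotide span on the
#' template. A target region (TR) is one codon or several nearby codons;
#' the span is capped at 12 nt (4 codons) since wider regions cannot be
#' carried by a single mutagenic oligo.
#'
#' @param unit A [transcription_unit()].
#' @param first_residue,last_residue 1-based residue numbers in the user's
#'   numbering (offset applied per CDS).
#' @param cds_index Which CDS the residues refer to.
#' @param max_span_nt Span cap in nt; override with care.
#' @return A `target_region` with the nucleotide span, codon count and
#'   wild-type codon/amino-acid content.
#' @export
resolve_target_region <- function(unit, first_residue, last_residue = first_residue,
                                  cds_index = 1L, max_span_nt = 12L) {
  stopifnot(inherits(unit, "transcription_unit"))
  if (first_residue < 1L || last_residue < 1L) {
    stop("residue numbering is 1-based", call. = FALSE)
  }
  if (last_residue < first_residue) stop("empty residue range", call. = FALSE)
  cds <- unit$cds[[cds_index]]
  off <- unit$cds_offset[cds_index]
  i1 <- first_residue - off; i2 <- last_residue - off   # 1-based codon indices
  n_codons <- (cds[2] - cds[1]) %/% 3L
  if (i1 < 1L || i2 > n_codons) {
    stop("residues ", first_residue, "..", last_residue,
         " fall outside CDS ", cds_index, " (", n_codons,
         " codons after offset ", off, ")", call. = FALSE)
  }
  span <- c(cds[1] + 3L * (i1 - 1L), cds[1] + 3L * i2)
  if (span[2] - span[1] > max_span_nt) {
    stop("TR exceeds ", max_span_nt, "-base span (", span[2] - span[1], " nt)",
         call. = FALSE)
  }
  wt <- substr(unclass(unit$sequence), span[1] + 1L, span[2])
  structure(list(cds_index = as.integer(cds_index),
                 first_residue = as.integer(first_residue),
                 last_residue = as.integer(last_residue),
                 span = as.integer(span),
                 wt_codons = dna(wt),
                 wt_aa = translate_dna(dna(wt))),
            class = "target_region")
}

#' @export
print.target_region <- function(x, ...) {
  cat(sprintf("<target_region> residues %d..%d (CDS %d), span [%d,%d), wt %s (%s)\n",
              x$first_residue, x$last_residue, x$cds_index, x$span[1], x$span[2],
              unclass(x$wt_codons), x$wt_aa))
  invisible(x)
}

#' Substitution set for a target region
#'
#' A list of enumerated payloads for one TR. Each payload is a replacement
#' of the TR's nucleotide span by an explicit sequence, which covers codon
#' substitution, insertion of codon runs (payload longer than the TR),
#' deletion/truncation (shorter), and whole-segment replacement.
#'
#' @param tr A `target_region`.
#' @param payloads Named list (or named character vector) of replacement
#'   sequences; names are variant labels, unique within the set. Each
#'   payload length must be a multiple of 3.
#' @return A `substitution_set`.
#' @seealso [saturation_set()] for the all-20-amino-acids case.
#' @export
substitution_set <- function(tr, payloads) {
  stopifnot(inherits(tr, "target_region"))
  if (length(payloads) == 0L) stop("payload list is empty", call. = FALSE)
  labels <- names(payloads)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == "")) {
    stop("payloads must have unique non-empty labels", call. = FALSE)
  }
  payloads <- lapply(payloads, as_dna)
  if (any(vapply(payloads, nchar, 0L) %% 3L != 0L)) {
    stop("payload lengths must be multiples of 3", call. = FALSE)
  }
  structure(list(tr = tr, payloads = payloads), class = "substitution_set")
}

#' Saturation substitution set
#'
#' One payload per amino acid in `aa_set` for a single-codon TR, using
#' codons from a [codon_choice_table()]. Labels follow the
#' `<residue><wtAA><mutAA>` convention (e.g. `108DN`). Alphabetical order
#' by single-letter code.
#'
#' @param tr A single-codon `target_region`.
#' @param aa_set Amino acids to include (default all 20).
#' @param table A [codon_choice_table()].
#' @return A `substitution_set`.
#' @export
saturation_set <- function(tr, aa_set = AA20, table = midas_codon_table()) {
  if (tr$span[2] - tr$span[1] != 3L) {
    stop("saturation_set targets a single-codon TR", call. = FALSE)
  }
  aa_set <- sort(unique(toupper(aa_set)))
  if (!all(aa_set %in% AA20)) stop("invalid amino acid in aa_set", call. = FALSE)
  payloads <- as.list(table$codons[aa_set])
  names(payloads) <- paste0(tr$wt_aa, tr$first_residue, aa_set)
  substitution_set(tr, payloads)
}

# apply one payload to the template sequence; returns the edited dna
apply_payload <- function(unit, tr, payload) {
  s <- unclass(unit$sequence)
  dna(paste0(substr(s, 1L, tr$span[1]), unclass(as_dna(payload)),
             substr(s, tr$span[2] + 1L, nchar(s))))
}
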