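#' Read a template transcription unit from a file
#'
#' FASTA input takes the feature annotations from the `features` argument;
#' GenBank input takes them from the feature table (keys `promoter`, `CDS`,
#' `polyA_signal`/`polyA`; simple forward `start..end` locations).
#' Sequences are canonicalized (case-insensitive).
#'
#' @param path File path.
#' @param format `"fasta"` or `"genbank"` (default guessed from the
#'   extension).
#' @param features For FASTA: data.frame with `type`, `start`, `end`
#'   (0-based half-open), as for [load_unit()].
#' @param cds_offset,name Passed to [load_unit()]; `name` defaults to the
#'   record id.
#' @return A [transcription_unit()].
#' @export
read_template <- function(path, format = NULL, features = NULL,
                          cds_offset = 0L, name = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE)) {
      "genbank"
    } else "fasta"
  }
  format <- match.arg(format, c("fasta", "genbank"))
  if (format == "fasta") {
    if (is.null(features)) {
      stop("FASTA input needs a `features` data.frame with columns ",
           "type, start, end (promoter, CDS, polyA)", call. = FALSE)
    }
    recs <- Biostrings::readDNAStringSet(path)
    if (length(recs) < 1L) stop("no sequence in ", path, call. = FALSE)
    seqn <- dna(as.character(recs[[1]]))
    nm <- name %||% sub("\\s.*$", "", names(recs)[1])
    load_unit(seqn, features, cds_offset = cds_offset, name = nm)
  } else {
    gb <- parse_genbank(path)
    load_unit(gb$sequence, gb$features, cds_offset = cds_offset,
              name = name %||% gb$name)
  }
}

# minimal GenBank flat-file parser: LOCUS name, simple forward-strand
# start..end features, ORIGIN sequence
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  nm <- if (length(locus)) strsplit(trimws(locus[1]), "[[:space:]]+")[[1]][2] else "genbank"
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(fstart) || !length(ostart)) {
    stop("GenBank record missing FEATURES or ORIGIN in ", path, call. = FALSE)
  }
  feat <- list()
  for (ln in lines[(fstart + 1L):(ostart - 1L)]) {
    m <- regmatches(ln, regexec("^\\s{5}(\\S+)\\s+(\\d+)\\.\\.(\\d+)", ln))[[1]]
    if (length(m) == 4L) {
      feat[[length(feat) + 1L]] <- data.frame(
        type = m[2], start = as.integer(m[3]) - 1L, end = as.integer(m[4]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(feat)) stop("no parsable features in ", path, call. = FALSE)
  features <- do.call(rbind, feat)
  features$type <- sub("^polyA_signal$", "polyA", features$type)
  seq_lines <- lines[(ostart + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seqn <- gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = ""))
  list(sequence = dna(seqn), features = features, name = nm)
}

#' Write a primer order sheet
#'
#' CSV with columns `name`, `sequence` (payload bases uppercase, template
#' bases lowercase), `plate`, `well`. Deterministic given inputs.
#'
#' @param primers List of [primer_spec()].
#' @param path Output CSV path.
#' @param plate_size Plate size for well assignment.
#' @param display `TRUE` for mixed-case payload highlighting, `FALSE` for
#'   plain lowercase.
#' @return The written data.frame, invisibly.
#' @export
write_order_sheet <- function(primers, path, plate_size = 96L, display = TRUE) {
  layout <- layout_plates(vapply(primers, function(p) p$name, ""),
                          plate_size = plate_size)
  df <- data.frame(
    name = layout$label,
    sequence = vapply(primers, function(p)
      if (display) primer_display(p) else tolower(unclass(p$sequence)), ""),
    plate = layout$plate, well = layout$well,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write an assembly plan as TSV
#'
#' One row per reaction (primaries then secondaries).
#'
#' @param plan An [plan_assembly()] result.
#' @param path Output TSV path.
#' @return The written data.frame, invisibly.
#' @export
write_plan_tsv <- function(plan, path) {
  pri <- data.frame(stage = "primary", id = plan$primary$id,
                    variant = plan$primary$variant,
                    fwd = plan$primary$fwd, rev = plan$primary$rev,
                    amplicons = NA_character_, stringsAsFactors = FALSE)
  sec <- data.frame(stage = "secondary", id = plan$secondary$variant,
                    variant = plan$secondary$variant,
                    fwd = plan$secondary$fwd, rev = plan$secondary$rev,
                    amplicons = plan$secondary$amplicons,
                    stringsAsFactors = FALSE)
  df <- rbind(pri, sec)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write / read an assembly plan as JSON
#'
#' The JSON form captures the template, substitution sets, primers and
#' reaction tables; [read_plan_json()] reconstructs an equivalent
#' [plan_assembly()] object.
#'
#' @param plan An `assembly_plan`.
#' @param path JSON path.
#' @return `write_plan_json()`: `path`, invisibly. `read_plan_json()`: an
#'   `assembly_plan`.
#' @export
write_plan_json <- function(plan, path) {
  ser_primer <- function(p) {
    list(name = p$name, sequence = unclass(p$sequence), role = p$role,
         anneal_span = p$anneal_span, strand = p$strand,
         payload = if (!is.null(p$payload)) unclass(p$payload),
         flanks = p$flanks, tag = if (!is.null(p$tag)) unclass(p$tag),
         overlap_partner = p$overlap_partner, overlap_tm = p$overlap_tm,
         tm_extended = p$tm_extended)
  }
  obj <- list(
    scheme = plan$scheme, mode = plan$mode,
    unit = list(sequence = unclass(plan$unit$sequence),
                promoter = plan$unit$promoter,
                cds = plan$unit$cds, polya = plan$unit$polya,
                cds_offset = plan$unit$cds_offset, name = plan$unit$name),
    sets = lapply(plan$sets, function(s) list(
      cds_index = s$tr$cds_index,
      first_residue = s$tr$first_residue, last_residue = s$tr$last_residue,
      payloads = lapply(s$payloads, unclass))),
    primers = lapply(plan$primers, ser_primer),
    primary = plan$primary, secondary = plan$secondary,
    counts = plan$counts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  u <- obj$unit
  unit <- transcription_unit(dna(u$sequence), promoter = unlist(u$promoter),
                             cds = lapply(u$cds, unlist),
                             polya = unlist(u$polya),
                             cds_offset = unlist(u$cds_offset), name = u$name)
  sets <- lapply(obj$sets, function(s) {
    tr <- resolve_target_region(unit, s$first_residue, s$last_residue,
                                cds_index = s$cds_index)
    substitution_set(tr, lapply(s$payloads, dna))
  })
  int_or_na <- function(x) vapply(x, function(v)
    if (is.null(v)) NA_integer_ else as.integer(v), 1L)
  primers <- lapply(obj$primers, function(p) {
    fl <- if (length(p$flanks) == 2L) int_or_na(p$flanks) else c(NA_integer_, NA_integer_)
    primer_spec(name = p$name, sequence = dna(p$sequence), role = p$role,
                anneal_span = if (!is.null(p$anneal_span)) int_or_na(p$anneal_span),
                strand = p$strand,
                payload = if (!is.null(p$payload)) dna(p$payload),
                flanks = fl,
                tag = if (!is.null(p$tag)) dna(p$tag),
                overlap_partner = p$overlap_partner %||% NA_character_,
                overlap_tm = p$overlap_tm %||% NA_real_,
                tm_extended = isTRUE(p$tm_extended))
  })
  names(primers) <- vapply(obj$primers, function(p) p$name, "")
  as_frame <- function(rows) {
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(lapply(r, function(x) x %||% NA), stringsAsFactors = FALSE)))
  }
  structure(list(scheme = obj$scheme, mode = obj$mode, unit = unit,
                 sets = sets, primers = primers,
                 outer = unlist(obj$outer),
                 primary = as_frame(obj$primary),
                 secondary = as_frame(obj$secondary),
                 counts = lapply(obj$counts, unlist)),
            class = "assembly_plan")
}

#' Write a plate map in grid form
#'
#' CSV matrix with plate rows as lines and one block per plate.
#'
#' @param layout A [layout_plates()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(layout) == 0L) {
    writeLines("plate,row", con)
    return(invisible(path))
  }
  ncol_p <- if (identical(attr(layout, "plate_size"), 384L)) 24L else 12L
  writeLines(paste(c("plate,row", seq_len(ncol_p)), collapse = ","), con)
  for (p in unique(layout$plate)) {
    sub <- layout[layout$plate == p, ]
    for (r in unique(sub$row)) {
      cells <- character(ncol_p)
      rowdat <- sub[sub$row == r, ]
      cells[rowdat$col] <- rowdat$label
      writeLines(paste(c(paste0(p, ",", r), cells), collapse = ","), con)
    }
  }
  invisible(path)
}

#' Write a score matrix as TSV
#'
#' @param m Site x substitution matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(m, path) {
  df <- data.frame(site = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
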