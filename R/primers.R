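#' Primer specification
#'
#' Record describing a designed oligo: role, annealing span on the
#' template, mutation payload, flank lengths, optional 5' tag extension,
#' and the overlap Tm with its partner primer where applicable.
#'
#' @param name Primer name.
#' @param sequence Full oligo [dna()] sequence (5'->3').
#' @param role One of `"Fo"`, `"Ro"`, `"Fo'"`, `"Ro'"`, `"F_mut"`,
#'   `"R_counter"`, `"F_counter"`, `"R_mut"`.
#' @param anneal_span Template span of the 3' annealing region (0-based
#'   half-open), or `NULL` for tag-only primers.
#' @param strand `"+"` or `"-"`.
#' @param payload Payload [dna()] carried by a mutagenic primer, or `NULL`.
#' @param flanks Integer `c(five_prime, three_prime)` flank lengths, nt.
#' @param tag Optional 5' tag [dna()] extension (must be a prefix of
#'   `sequence`).
#' @param overlap_partner Name of the partner primer for the overlap rule.
#' @param overlap_tm Overlap melting temperature, degC.
#' @param tm_extended `TRUE` when a flank was grown beyond the standard
#'   upper bound to reach the Tm target.
#' @return A `primer_spec`.
#' @export
primer_spec <- function(name, sequence, role, anneal_span = NULL, strand = "+",
                        payload = NULL, flanks = c(NA_integer_, NA_integer_),
                        tag = NULL, overlap_partner = NA_character_,
                        overlap_tm = NA_real_, tm_extended = FALSE) {
  sequence <- as_dna(sequence)
  role <- match.arg(role, c("Fo", "Ro", "Fo'", "Ro'",
                            "F_mut", "R_counter", "F_counter", "R_mut"))
  if (!is.null(tag)) {
    tag <- as_dna(tag)
    if (!startsWith(unclass(sequence), unclass(tag))) {
      stop("tag must be a prefix of the primer sequence", call. = FALSE)
    }
  }
  structure(list(name = name, sequence = sequence, role = role,
                 anneal_span = anneal_span, strand = strand,
                 payload = if (!is.null(payload)) as_dna(payload),
                 flanks = as.integer(flanks), tag = tag,
                 overlap_partner = overlap_partner,
                 overlap_tm = overlap_tm, tm_extended = isTRUE(tm_extended)),
            class = "primer_spec")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat(sprintf("<primer_spec %s> [%s] %d nt%s\n  %s\n", x$name, x$role,
              nchar(x$sequence),
              if (!is.null(x$tag)) sprintf(" (tag %d nt)", nchar(x$tag)) else "",
              primer_display(x)))
  invisible(x)
}

#' Order-sheet display form of a primer
#'
#' Template-matching bases in lowercase, payload bases in UPPERCASE,
#' matching the conventional mutagenic-oligo notation.
#'
#' @param spec A [primer_spec()].
#' @return Character scalar.
#' @export
primer_display <- function(spec) {
  s <- tolower(unclass(spec$sequence))
  if (!is.null(spec$payload) && !is.na(spec$flanks[1])) {
    start <- (if (!is.null(spec$tag)) nchar(spec$tag) else 0L) + spec$flanks[1]
    pl <- nchar(spec$payload)
    if (pl > 0L) {
      substr(s, start + 1L, start + pl) <- toupper(substr(s, start + 1L, start + pl))
    }
  }
  s
}

# default flank/Tm constraints for mutagenic, counter, and outer primers
#' Primer design constraints
#'
#' @param flank_bounds Standard flank-length window, nt (flanks start at the
#'   lower bound in auto mode and grow until the overlap Tm target is met).
#' @param flank_max Hard upper limit on flank growth, nt.
#' @param tm_window Target overlap/anneal Tm window, degC. Growth stops at
#'   the lower edge; exceeding the upper edge at minimum length warns but
#'   never shortens below the lower flank bound.
#' @param params A [tm_params()].
#' @return A `primer_constraints` list.
#' @export
primer_constraints <- function(flank_bounds = c(18L, 24L), flank_max = 40L,
                               tm_window = c(60, 66), params = tm_params()) {
  structure(list(flank_bounds = as.integer(flank_bounds),
                 flank_max = as.integer(flank_max),
                 tm_window = tm_window, params = params),
            class = "primer_constraints")
}

# choose the shortest length in [lo, max] whose Tm of pick(L) >= tm low edge;
# returns list(length, tm, extended) -- extended = grew past standard bounds
auto_flank_length <- function(pick, cons) {
  lo <- cons$flank_bounds[1]; hi <- cons$flank_bounds[2]; mx <- cons$flank_max
  for (L in lo:mx) {
    s <- pick(L)
    if (is.null(s)) break
    tm <- melting_temperature(s, cons$params)
    if (tm >= cons$tm_window[1]) {
      if (L == lo && tm > cons$tm_window[2]) {
        warning("overlap Tm ", round(tm, 1), " degC above the ",
                cons$tm_window[2], " degC window at minimum flank length; ",
                "keeping ", lo, " nt", call. = FALSE)
      }
      if (L > hi) {
        warning("flank extended to ", L, " nt (beyond ", hi,
                " nt) to reach Tm >= ", cons$tm_window[1], " degC",
                call. = FALSE)
      }
      return(list(length = L, tm = tm, extended = L > hi))
    }
  }
  stop("Tm >= ", cons$tm_window[1], " degC unreachable within ",
       mx, " nt flank", call. = FALSE)
}

#' Design a mutagenic primer
#'
#' Builds the mutation-carrying primer for a target region: a 5' flank
#' taken from the template immediately upstream of the TR, the payload
#' codons, and a 3' annealing arm matching the template immediately
#' downstream (mirror-symmetric in reverse orientation, where the payload
#' rides on the reverse primer). Flank lengths may be given explicitly or
#' chosen automatically: start at the lower bound and grow until the flank
#' Tm reaches the window.
#'
#' @param unit A [transcription_unit()].
#' @param tr A `target_region`.
#' @param payload Replacement sequence for the TR span.
#' @param label Variant label used in the primer name.
#' @param orientation `"forward"` (payload on F, default — matching typical
#'   array layouts) or `"reverse"`.
#' @param flanks Explicit `c(five_prime, three_prime)` flank lengths, or
#'   `NULL` for Tm-driven auto selection.
#' @param constraints A [primer_constraints()].
#' @return A [primer_spec()] with role `"F_mut"` or `"R_mut"`.
#' @export
design_mutagenic_primer <- function(unit, tr, payload, label = "variant",
                                    orientation = c("forward", "reverse"),
                                    flanks = NULL,
                                    constraints = primer_constraints()) {
  orientation <- match.arg(orientation)
  payload <- as_dna(payload)
  s <- unclass(unit$sequence)
  up_avail <- tr$span[1]
  down_avail <- nchar(s) - tr$span[2]
  pick_up <- function(L) if (L <= up_avail) dna(substr(s, tr$span[1] - L + 1L, tr$span[1]))
  pick_down <- function(L) if (L <= down_avail) dna(substr(s, tr$span[2] + 1L, tr$span[2] + L))
  extended <- FALSE
  if (is.null(flanks)) {
    a5 <- auto_flank_length(if (orientation == "forward") pick_up else pick_down, constraints)
    a3 <- auto_flank_length(if (orientation == "forward") pick_down else pick_up, constraints)
    f5 <- a5$length; f3 <- a3$length
    extended <- a5$extended || a3$extended
    overlap_tm <- a5$tm
  } else {
    f5 <- as.integer(flanks[1]); f3 <- as.integer(flanks[2])
    if (orientation == "forward") {
      if (f5 > up_avail || f3 > down_avail) stop("flank exceeds template", call. = FALSE)
      overlap_tm <- melting_temperature(pick_up(f5), constraints$params)
    } else {
      if (f5 > down_avail || f3 > up_avail) stop("flank exceeds template", call. = FALSE)
      overlap_tm <- melting_temperature(pick_down(f5), constraints$params)
    }
  }
  if (orientation == "forward") {
    seqn <- dna(paste0(pick_up(f5), payload, pick_down(f3)))
    span <- c(tr$span[1] - f5, tr$span[2] + f3)
    role <- "F_mut"; strand <- "+"
  } else {
    seqn <- dna(paste0(revcomp(pick_down(f5)), revcomp(payload), revcomp(pick_up(f3))))
    span <- c(tr$span[1] - f3, tr$span[2] + f5)
    role <- "R_mut"; strand <- "-"
    payload <- revcomp(payload)
  }
  primer_spec(name = paste0(unit$name, "-", label, if (orientation == "forward") "-F" else "-R"),
              sequence = seqn, role = role, anneal_span = as.integer(span),
              strand = strand, payload = payload, flanks = c(f5, f3),
              overlap_tm = overlap_tm, tm_extended = extended)
}

#' Design the non-mutagenic counter primer
#'
#' The counter primer pairs with a mutagenic primer array at the same TR:
#' its sequence is the reverse complement of the template window ending
#' immediately before the TR (for forward-mutagenic arrays), so that its
#' 5' region is reverse-complementary to the shared 5' flank of every
#' sibling mutagenic primer, with an overlap melting temperature inside
#' the target window.
#'
#' @param unit A [transcription_unit()].
#' @param tr The `target_region` the partner array mutates.
#' @param partner A mutagenic [primer_spec()] from the array.
#' @param length Explicit counter-primer length, or `NULL` for Tm-driven
#'   selection.
#' @param constraints A [primer_constraints()].
#' @return A [primer_spec()] with role `"R_counter"` (or `"F_counter"` for
#'   reverse-mutagenic arrays).
#' @export
design_counter_primer <- function(unit, tr, partner, length = NULL,
                                  constraints = primer_constraints()) {
  stopifnot(inherits(partner, "primer_spec"))
  s <- unclass(unit$sequence)
  if (partner$role == "F_mut") {
    pick <- function(L) if (L <= tr$span[1]) dna(substr(s, tr$span[1] - L + 1L, tr$span[1]))
    role <- "R_counter"; strand <- "-"
  } else if (partner$role == "R_mut") {
    pick <- function(L) if (tr$span[2] + L <= nchar(s)) dna(substr(s, tr$span[2] + 1L, tr$span[2] + L))
    role <- "F_counter"; strand <- "+"
  } else stop("partner must be a mutagenic primer", call. = FALSE)
  extended <- FALSE
  if (is.null(length)) {
    a <- auto_flank_length(pick, constraints)
    L <- a$length; tm <- a$tm; extended <- a$extended
  } else {
    L <- as.integer(length)
    win <- pick(L)
    if (is.null(win)) stop("counter-primer length exceeds template", call. = FALSE)
    tm <- melting_temperature(win, constraints$params)
  }
  win <- pick(L)
  seqn <- if (role == "R_counter") revcomp(win) else win
  span <- if (role == "R_counter") c(tr$span[1] - L, tr$span[1]) else c(tr$span[2], tr$span[2] + L)
  primer_spec(name = paste0(unit$name, "-", tr$wt_aa, tr$first_residue, "-",
                            if (role == "R_counter") "R" else "F"),
              sequence = seqn, role = role, anneal_span = as.integer(span),
              strand = strand, flanks = c(L, L),
              overlap_partner = partner$name, overlap_tm = tm,
              tm_extended = extended)
}

#' Design a saturation mutagenesis primer array
#'
#' One mutagenic primer per amino acid in `aa_set`, all sharing identical
#' flanks so that a single counter primer serves the whole array;
#' deterministic alphabetical order.
#'
#' @inheritParams design_mutagenic_primer
#' @param aa_set Amino acids to enumerate (default all 20, including the
#'   wild-type identity substitution).
#' @param table A [codon_choice_table()].
#' @return List of [primer_spec()], names `<residue><wtAA><mutAA>`.
#' @export
design_saturation_array <- function(unit, tr, aa_set = AA20,
                                    table = midas_codon_table(),
                                    orientation = "forward", flanks = NULL,
                                    constraints = primer_constraints()) {
  ss <- saturation_set(tr, aa_set, table)
  if (is.null(flanks)) {
    # fix flanks once from the first payload so the array shares them
    first <- design_mutagenic_primer(unit, tr, ss$payloads[[1]],
                                     label = names(ss$payloads)[1],
                                     orientation = orientation,
                                     constraints = constraints)
    flanks <- first$flanks
  }
  out <- lapply(seq_along(ss$payloads), function(i) {
    design_mutagenic_primer(unit, tr, ss$payloads[[i]],
                            label = names(ss$payloads)[i],
                            orientation = orientation, flanks = flanks,
                            constraints = constraints)
  })
  stats::setNames(out, names(ss$payloads))
}

#' Generate a template-absent tag sequence
#'
#' Seeded pseudo-random tag (GC content 40-60 percent) screened by
#' exhaustive substring match against the template on both strands: the
#' tag is accepted when no exact shared substring reaches `stringency` nt.
#'
#' @param unit A [transcription_unit()].
#' @param seed Integer seed; tags are deterministic given the seed.
#' @param length Tag length, nt.
#' @param stringency Maximum tolerated shared exact substring + 1 (a tag
#'   passes when the longest shared run is `< stringency`).
#' @param retries Candidate tags to try before giving up.
#' @return A `dna` tag.
#' @export
generate_tag <- function(unit, seed = 1L, length = 23L, stringency = 12L,
                         retries = 100L) {
  rng <- local({ set.seed(seed); function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE) })
  for (i in seq_len(retries)) {
    cand <- paste(rng(length), collapse = "")
    gc <- sum(strsplit(cand, "")[[1]] %in% c("G", "C")) / length
    if (gc < 0.4 || gc > 0.6) next
    rep <- validate_tag(dna(cand), unit, stringency = stringency)
    if (rep$pass) return(dna(cand))
  }
  stop("no template-absent tag found in ", retries, " attempts", call. = FALSE)
}

#' Validate a tag against a template
#'
#' Reports the longest exact substring shared between the tag (either
#' strand) and the template; the tag passes when that length is below the
#' stringency threshold, so nested primers priming on the tag cannot find
#' a foothold on the template.
#'
#' @param tag Tag [dna()] sequence (>= 15 nt).
#' @param unit A [transcription_unit()].
#' @param stringency Pass threshold: longest shared run must be
#'   `< stringency` nt.
#' @return List with `longest_match` (nt), `pass`, `stringency`.
#' @export
validate_tag <- function(tag, unit, stringency = 12L) {
  tag <- as_dna(tag)
  if (nchar(tag) < 15L) stop("tag must be >= 15 nt", call. = FALSE)
  templ <- unclass(unit$sequence)
  templ_rc <- unclass(revcomp(unit$sequence))
  n <- nchar(tag)
  longest <- 0L
  for (k in seq_len(n)) {
    subs <- unique(substring(unclass(tag), 1:(n - k + 1L), k:n))
    hit <- any(vapply(subs, function(x) grepl(x, templ, fixed = TRUE) ||
                        grepl(x, templ_rc, fixed = TRUE), logical(1)))
    if (hit) longest <- k else break
  }
  list(longest_match = longest, pass = longest < stringency,
       stringency = as.integer(stringency))
}

#' Design outer (and nested) primers
#'
#' Fo anneals at the 5' end of the promoter region and Ro at the 3' end of
#' the polyadenylation signal, bracketing the whole transcription unit. In
#' monotemplated mode, 5' tag extensions absent from the template are
#' attached per `tag_policy`, and nested Fo'/Ro' primers that prime only on
#' the tags are emitted; secondary PCRs primed by them cannot re-amplify
#' the plasmid template.
#'
#' @param unit A [transcription_unit()].
#' @param mode `"polytemplated"` (no tags) or `"monotemplated"`.
#' @param tag_policy Which outer primers carry tags: `"both"`, `"fo"`, `"ro"`.
#' @param tags Optional named list `list(fo = , ro = )` of explicit tag
#'   sequences; missing tags are generated with [generate_tag()].
#' @param seed Seed for tag generation.
#' @param nested_extension Extra template-matching bases appended inward of
#'   the tag on Fo'/Ro' (default 0: nested primers are exactly the tag).
#' @param constraints A [primer_constraints()].
#' @return Named list of [primer_spec()]: `Fo`, `Ro`, plus `Fo'`/`Ro'` in
#'   monotemplated mode.
#' @export
design_outer_primers <- function(unit, mode = c("polytemplated", "monotemplated"),
                                 tag_policy = c("both", "fo", "ro"),
                                 tags = list(), seed = 1L, nested_extension = 0L,
                                 constraints = primer_constraints()) {
  mode <- match.arg(mode)
  tag_policy <- match.arg(tag_policy)
  s <- unclass(unit$sequence)
  n <- nchar(s)
  pick_fo <- function(L) if (unit$promoter[1] + L <= n) dna(substr(s, unit$promoter[1] + 1L, unit$promoter[1] + L))
  pick_ro <- function(L) if (unit$polya[2] - L >= 0L) dna(substr(s, unit$polya[2] - L + 1L, unit$polya[2]))
  afo <- auto_flank_length(pick_fo, constraints)
  aro <- auto_flank_length(pick_ro, constraints)
  fo_core <- pick_fo(afo$length); ro_core <- revcomp(pick_ro(aro$length))
  fo_span <- c(unit$promoter[1], unit$promoter[1] + afo$length)
  ro_span <- c(unit$polya[2] - aro$length, unit$polya[2])
  out <- list()
  if (mode == "polytemplated") {
    out$Fo <- primer_spec(paste0(unit$name, "-Fo"), fo_core, "Fo",
                          anneal_span = as.integer(fo_span), strand = "+",
                          overlap_tm = afo$tm)
    out$Ro <- primer_spec(paste0(unit$name, "-Ro"), ro_core, "Ro",
                          anneal_span = as.integer(ro_span), strand = "-",
                          overlap_tm = aro$tm)
    return(out)
  }
  want_fo_tag <- tag_policy %in% c("both", "fo")
  want_ro_tag <- tag_policy %in% c("both", "ro")
  get_tag <- function(which, offset) {
    if (!is.null(tags[[which]])) {
      tg <- as_dna(tags[[which]])
      rep <- validate_tag(tg, unit)
      if (!rep$pass) stop("supplied ", which, " tag shares a ", rep$longest_match,
                          "-nt run with the template", call. = FALSE)
      tg
    } else generate_tag(unit, seed = seed + offset)
  }
  fo_tag <- if (want_fo_tag) get_tag("fo", 0L)
  ro_tag <- if (want_ro_tag) get_tag("ro", 1000L)
  out$Fo <- primer_spec(paste0(unit$name, "-Fo"),
                        dna(paste0(if (want_fo_tag) fo_tag else "", fo_core)),
                        "Fo", anneal_span = as.integer(fo_span), strand = "+",
                        tag = fo_tag, overlap_tm = afo$tm)
  out$Ro <- primer_spec(paste0(unit$name, "-Ro"),
                        dna(paste0(if (want_ro_tag) ro_tag else "", ro_core)),
                        "Ro", anneal_span = as.integer(ro_span), strand = "-",
                        tag = ro_tag, overlap_tm = aro$tm)
  ext <- as.integer(nested_extension)
  if (want_fo_tag) {
    seqn <- dna(paste0(fo_tag, substr(unclass(fo_core), 1L, ext)))
    out[["Fo'"]] <- primer_spec(paste0(unit$name, "-Fo'"), seqn, "Fo'",
                                strand = "+", tag = fo_tag)
  }
  if (want_ro_tag) {
    seqn <- dna(paste0(ro_tag, substr(unclass(ro_core), 1L, ext)))
    out[["Ro'"]] <- primer_spec(paste0(unit$name, "-Ro'"), seqn, "Ro'",
                                strand = "-", tag = ro_tag)
  }
  out
}
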