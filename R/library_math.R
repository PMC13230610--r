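#' Error-prone PCR recovery model
#'
#' Model for the per-clone frequency at which a specific multi-nucleotide
#' amino-acid change is recovered from a random-mutagenesis library:
#' each required base change costs one mutation event (per-nucleotide rate)
#' that must land in a functional clone (functional fraction), hit the
#' right position, and land on an acceptable base (`a_i` of 4), with a path
#' multiplicity `m` when several mutually exclusive codon paths reach the
#' same amino acid.
#'
#' @param rate Per-nucleotide mutagenesis rate (fraction in (0,1)).
#' @param functional Fraction of library clones remaining functional at
#'   that rate.
#' @param n Number of required base changes (>= 1).
#' @param acceptable Integer vector of length `n`; `acceptable[i]` in 1..4
#'   is the number of target bases acceptable at change `i` (4 = any base).
#' @param paths Path multiplicity `m` (>= 1).
#' @return An `epcr_model`.
#' @export
epcr_model <- function(rate, functional, n = 1L, acceptable = rep(4L, n),
                       paths = 1L) {
  if (rate <= 0 || rate >= 1 || functional <= 0 || functional >= 1) {
    stop("rate and functional fraction must lie in (0, 1)", call. = FALSE)
  }
  n <- as.integer(n)
  acceptable <- as.integer(acceptable)
  if (n < 1L || length(acceptable) != n || any(acceptable < 1L | acceptable > 4L)) {
    stop("need n >= 1 acceptable-base counts, each in 1..4", call. = FALSE)
  }
  if (paths < 1L) stop("path multiplicity must be >= 1", call. = FALSE)
  structure(list(rate = rate, functional = functional, n = n,
                 acceptable = acceptable, paths = as.integer(paths)),
            class = "epcr_model")
}

# round to k significant figures
signif_k <- function(x, k) signif(x, k)

#' Recovery frequency of a specific change under error-prone PCR
#'
#' frequency = (rate x functional)^n x prod(acceptable_i / 4) x paths.
#' The reciprocal is reported as a "1 in N" figure: N rounded to one
#' significant figure below 1e5 and two significant figures above,
#' matching the conventional precision of such estimates; the exact value
#' is returned alongside.
#'
#' @param model An [epcr_model()].
#' @param signif_small,signif_large Significant figures used for the
#'   rounded "1 in N" below/above the `switchover`.
#' @param switchover N above which `signif_large` applies.
#' @return List with `frequency`, `one_in` (exact N) and
#'   `one_in_rounded`.
#' @examples
#' # a two-base change with one acceptable base at one position and two at
#' # the other, at a 0.5% mutagenesis rate keeping 6.7% of clones functional
#' epcr_recovery(epcr_model(0.005, 0.067, n = 2, acceptable = c(1, 2)))
#' @export
epcr_recovery <- function(model, signif_small = 1L, signif_large = 2L,
                          switchover = 1e5) {
  stopifnot(inherits(model, "epcr_model"))
  freq <- (model$rate * model$functional)^model$n *
    prod(model$acceptable / 4) * model$paths
  one_in <- 1 / freq
  k <- if (one_in < switchover) signif_small else signif_large
  list(frequency = freq, one_in = one_in, one_in_rounded = signif_k(one_in, k))
}

#' Degenerate-library description
#'
#' @param positions Number of saturated positions P.
#' @param codons_per_position Degenerate codons per position (32 for
#'   NNS/NNK).
#' @param oversampling Oversampling factor overcoming Poisson sampling
#'   noise (10 gives ~99 percent coverage).
#' @return A `degenerate_library`.
#' @export
degenerate_library <- function(positions, codons_per_position = 32L,
                               oversampling = 10L) {
  if (positions < 0L || codons_per_position < 1L || oversampling < 1L) {
    stop("library parameters must be positive (positions may be 0)", call. = FALSE)
  }
  structure(list(positions = as.integer(positions),
                 codons_per_position = as.integer(codons_per_position),
                 oversampling = as.integer(oversampling)),
            class = "degenerate_library")
}

#' Samples needed to screen a degenerate library
#'
#' codons^P x oversampling: the cell/sample count required so that all
#' codon combinations at P degenerate positions are represented.
#'
#' @param lib A [degenerate_library()].
#' @return Numeric sample count.
#' @examples
#' degenerate_library_samples(degenerate_library(1))   # 320
#' degenerate_library_samples(degenerate_library(2))   # 10240
#' @export
degenerate_library_samples <- function(lib) {
  stopifnot(inherits(lib, "degenerate_library"))
  as.numeric(lib$codons_per_position)^lib$positions * lib$oversampling
}

#' Well count for an enumerated (arrayed) screen
#'
#' Deterministic construction needs exactly one well per variant: the
#' product of the substitution-set sizes for combinatorial screens, or the
#' sum when sites are screened independently.
#'
#' @param set_sizes Integer vector of per-site substitution counts, or a
#'   list of [substitution_set()].
#' @param combinatorial `TRUE` for all combinations (product), `FALSE` for
#'   independent per-site arrays (sum).
#' @return Numeric well count.
#' @examples
#' midas_sample_count(c(20, 20))                       # 400
#' midas_sample_count(rep(20, 25), combinatorial = FALSE)  # 500
#' @export
midas_sample_count <- function(set_sizes, combinatorial = TRUE) {
  if (is.list(set_sizes)) {
    set_sizes <- vapply(set_sizes, function(s) length(s$payloads), integer(1))
  }
  if (length(set_sizes) == 0L || any(set_sizes < 1L)) {
    stop("set sizes must be nonempty positive integers", call. = FALSE)
  }
  if (combinatorial) prod(as.numeric(set_sizes)) else sum(as.numeric(set_sizes))
}

#' Responsivity fold between two percent responses
#'
#' Ratio of two responsivities (e.g. percent luminescence increases of an
#' improved variant vs its parent). Both the exact ratio and a rounded
#' integer fold are returned; rounding mode is explicit because reported
#' folds are sometimes floored rather than rounded.
#'
#' @param new,old Responses (same units); `old > 0`.
#' @param rounding `"round"` or `"floor"`.
#' @return List with `fold` (exact) and `fold_rounded`.
#' @examples
#' responsivity_fold(640, 22)   # 29-fold
#' @export
responsivity_fold <- function(new, old, rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  if (old <= 0) stop("`old` must be > 0", call. = FALSE)
  fold <- new / old
  list(fold = fold,
       fold_rounded = if (rounding == "round") round(fold) else floor(fold))
}
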