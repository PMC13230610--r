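#' Normalize a signal to its vehicle control
#'
#' `fold` mode returns s/s0; `percent-increase` returns (s/s0 - 1) x 100.
#' The two are mutually consistent: percent = (fold - 1) x 100.
#'
#' @param signal,control_signal Signals; `control_signal > 0`.
#' @param mode `"fold"` or `"percent-increase"`.
#' @return Normalized response (vectorized).
#' @export
normalize_response <- function(signal, control_signal,
                               mode = c("fold", "percent-increase")) {
  mode <- match.arg(mode)
  if (any(control_signal <= 0)) stop("control signal must be > 0", call. = FALSE)
  fold <- signal / control_signal
  if (mode == "fold") fold else (fold - 1) * 100
}

#' Expression-normalize a signal
#'
#' Divides the reporter signal by a co-expressed reference signal (e.g. a
#' second, substrate-orthogonal luciferase translated from the same
#' amplicon), cancelling per-well transfection-efficiency differences
#' before variants are compared.
#'
#' @param signal,reference_signal Signals; `reference_signal > 0`.
#' @return Activity ratio (vectorized).
#' @export
expression_normalize <- function(signal, reference_signal) {
  if (any(reference_signal <= 0)) stop("reference signal must be > 0", call. = FALSE)
  signal / reference_signal
}

#' Score matrix from a tidy screen table
#'
#' Collapses a well-level screen table to a site x substitution activity
#' matrix for one condition: technical replicates of the
#' expression-normalized signal are averaged per variant, then divided by
#' the parent (wild-type) activity measured under the same condition.
#'
#' @param screen data.frame with columns `site`, `substitution`,
#'   `condition`, `signal`, `reference_signal`; parent wells carry
#'   `substitution == "WT"` (any site).
#' @param condition Condition (substrate) to score.
#' @param parent_label `substitution` value marking parent wells.
#' @return Matrix (sites x substitutions) of parent-relative activities,
#'   with attribute `parent_activity` (the raw parent ratio) and `cv` (a
#'   congruent matrix of per-variant replicate coefficients of variation).
#' @export
screen_score_matrix <- function(screen, condition, parent_label = "WT") {
  sub <- screen[screen$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for condition ", condition, call. = FALSE)
  act <- expression_normalize(sub$signal, sub$reference_signal)
  is_parent <- sub$substitution == parent_label
  if (!any(is_parent)) stop("no parent wells (substitution == '",
                            parent_label, "')", call. = FALSE)
  parent_activity <- mean(act[is_parent])
  if (parent_activity <= 0) stop("parent activity must be > 0", call. = FALSE)
  v <- sub[!is_parent, , drop = FALSE]
  vact <- act[!is_parent]
  sites <- unique(v$site)
  subs <- sort(unique(v$substitution))
  m <- matrix(NA_real_, length(sites), length(subs),
              dimnames = list(sites, subs))
  cv <- m
  for (s in sites) for (a in subs) {
    x <- vact[v$site == s & v$substitution == a]
    if (length(x)) {
      m[s, a] <- mean(x) / parent_activity
      cv[s, a] <- if (length(x) > 1L) stats::sd(x) / mean(x) else NA_real_
    }
  }
  attr(m, "parent_activity") <- parent_activity
  attr(m, "cv") <- cv
  m
}

#' Per-site mutational tolerance
#'
#' Aggregates a site x substitution activity matrix into per-site tolerance:
#' the sum and the mean of the wild-type-normalized activities of the
#' substitutions at each site. The mean is the scale-free headline score;
#' the sum over the 20 substitutions is reported alongside. The wild-type
#' identity substitution appears in enumerated arrays and is included by
#' default; `include_wt = FALSE` drops it when `wt_aa` names each site's
#' wild-type residue.
#'
#' @param m Site x substitution matrix of activities relative to wild type
#'   (as from [screen_score_matrix()]).
#' @param wt_activity Wild-type activity on the matrix scale (1 when the
#'   matrix is already parent-relative).
#' @param include_wt Keep each site's identity substitution in the
#'   aggregate.
#' @param wt_aa Named character vector site -> wild-type amino acid
#'   (required when `include_wt = FALSE`).
#' @return data.frame: `site`, `n` (substitutions present), `mean`, `sum`,
#'   ordered as in `m`.
#' @export
tolerance_scores <- function(m, wt_activity = 1, include_wt = TRUE,
                             wt_aa = NULL) {
  if (wt_activity <= 0) stop("wt activity must be > 0", call. = FALSE)
  if (!include_wt && is.null(wt_aa)) {
    stop("`wt_aa` needed to exclude the identity substitution", call. = FALSE)
  }
  rows <- lapply(rownames(m), function(s) {
    x <- m[s, ] / wt_activity
    if (!include_wt) x <- x[names(x) != wt_aa[[s]]]
    x <- x[!is.na(x)]
    data.frame(site = s, n = length(x), mean = mean(x), sum = sum(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Substrate-specificity matrix with censoring
#'
#' Compares parent-relative activity matrices across substrates. A variant
#' is censored when its activity falls below `censor_threshold` x parent on
#' any substrate (strictly below), avoiding error propagation from the high
#' coefficients of variation of dim wells. For retained variants the
#' preference for substrate X over Y is the ratio of parent-relative
#' activities (antisymmetric: pref(X,Y) x pref(Y,X) = 1); a variant
#' "prefers" X when its preference over every other substrate exceeds 1.
#'
#' @param matrices Named list of congruent site x substitution matrices of
#'   parent-relative activities, one per substrate.
#' @param censor_threshold Censoring threshold on the parent-relative
#'   scale.
#' @return A `specificity_matrix` list: `relative` (the input matrices),
#'   `censored` (logical matrix), `preferred` (character matrix: preferred
#'   substrate or NA), and `preference(X, Y)` accessor via
#'   [preference_score()].
#' @export
specificity_matrix <- function(matrices, censor_threshold = 0.25) {
  if (length(matrices) < 2L || is.null(names(matrices))) {
    stop("need >= 2 named substrate matrices", call. = FALSE)
  }
  dims <- lapply(matrices, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("substrate matrices must be congruent", call. = FALSE)
  }
  censored <- Reduce(`|`, lapply(matrices, function(m) m < censor_threshold))
  censored[is.na(censored)] <- TRUE
  preferred <- matrix(NA_character_, nrow(censored), ncol(censored),
                      dimnames = dimnames(censored))
  subs <- names(matrices)
  for (i in seq_len(nrow(censored))) for (j in seq_len(ncol(censored))) {
    if (censored[i, j]) next
    vals <- vapply(matrices, function(m) m[i, j], 0)
    top <- which.max(vals)
    if (all(vals[top] > vals[-top])) preferred[i, j] <- subs[top]
  }
  structure(list(relative = matrices, censored = censored,
                 preferred = preferred,
                 censor_threshold = censor_threshold),
            class = "specificity_matrix")
}

#' Preference score of one substrate over another
#'
#' @param spec A [specificity_matrix()].
#' @param x,y Substrate names.
#' @return Matrix of pref(x over y) = rel_x / rel_y; censored cells NA.
#' @export
preference_score <- function(spec, x, y) {
  stopifnot(inherits(spec, "specificity_matrix"))
  out <- spec$relative[[x]] / spec$relative[[y]]
  out[spec$censored] <- NA_real_
  out
}

#' Four-parameter logistic (variable-slope) dose-response fit
#'
#' Least-squares fit of response = bottom + (top - bottom) /
#' (1 + 10^((log10(EC50) - log10(dose)) * hill)) on log dose, the
#' "log(agonist/inhibitor) vs response - variable slope" model.
#' Initialization: bottom/top from the response extremes, EC50 from the
#' dose nearest the half-range crossing, hill = 1; parameters are bounded
#' (EC50 within the tested dose range, extended one decade each way).
#'
#' @param doses Dose vector (> 0), >= 4 distinct levels spanning the
#'   transition.
#' @param responses Response vector, same length.
#' @param hill_sign Constrain the slope sign: `"free"`, `"positive"`
#'   (agonist-like), `"negative"`.
#' @return List with `bottom`, `top`, `ec50`, `hill`, `fitted`,
#'   `residual_sd`, `converged`, and the underlying `fit` object.
#' @export
fit_dose_response <- function(doses, responses,
                              hill_sign = c("free", "positive", "negative")) {
  hill_sign <- match.arg(hill_sign)
  if (any(doses <= 0)) stop("doses must be > 0 (log scale)", call. = FALSE)
  if (length(unique(doses)) < 4L) {
    stop("need >= 4 distinct dose levels", call. = FALSE)
  }
  ld <- log10(doses)
  df <- data.frame(ld = ld, y = responses)
  b0 <- min(responses); t0 <- max(responses)
  half <- (b0 + t0) / 2
  e0 <- ld[which.min(abs(responses - half))]
  lower <- c(bottom = -Inf, top = -Inf, lec50 = min(ld) - 1, hill = -Inf)
  upper <- c(bottom = Inf, top = Inf, lec50 = max(ld) + 1, hill = Inf)
  if (hill_sign == "positive") lower["hill"] <- 1e-3
  if (hill_sign == "negative") upper["hill"] <- -1e-3
  fit <- try(minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + 10^((lec50 - ld) * hill)),
    data = df,
    start = list(bottom = b0, top = t0, lec50 = e0, hill = 1),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
                hill = NA_real_, fitted = rep(NA_real_, length(doses)),
                residual_sd = NA_real_, converged = FALSE,
                message = attr(fit, "condition")$message, fit = NULL))
  }
  cf <- stats::coef(fit)
  list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
       ec50 = unname(10^cf["lec50"]), hill = unname(cf["hill"]),
       fitted = stats::fitted(fit),
       residual_sd = stats::sigma(fit),
       converged = fit$convInfo$isConv %||% TRUE, fit = fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
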