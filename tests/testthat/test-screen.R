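test_that("vehicle normalization modes are mutually consistent", {
  expect_equal(normalize_response(7.4, 1, "percent-increase"), 640)
  expect_equal(normalize_response(7.4, 1, "fold"), 7.4)
  expect_equal(normalize_response(1.22, 1, "percent-increase"), 22)
  expect_equal(normalize_response(5, 5, "fold"), 1)
  expect_equal(normalize_response(5, 5, "percent-increase"), 0)
  set.seed(2)
  s <- runif(20, 0.1, 10); s0 <- runif(20, 0.5, 2)
  expect_equal(normalize_response(s, s0, "percent-increase"),
               (normalize_response(s, s0, "fold") - 1) * 100)
  expect_error(normalize_response(1, 0), "> 0")
})

test_that("expression normalization cancels shared transfection factors", {
  expect_equal(expression_normalize(100, 100), 1)
  set.seed(3)
  sig <- runif(10, 100, 1000); ref <- runif(10, 100, 1000)
  f <- runif(10, 0.2, 5)   # per-well transfection multiplier
  expect_equal(expression_normalize(sig * f, ref * f),
               expression_normalize(sig, ref))
  expect_error(expression_normalize(1, 0), "> 0")
})

test_that("tolerance aggregates behave on degenerate matrices", {
  m <- matrix(1, 2, 20, dimnames = list(c("s1", "s2"), LETTERS[1:20]))
  tol <- tolerance_scores(m)
  expect_equal(tol$mean, c(1, 1))
  expect_equal(tol$sum, c(20, 20))
  m2 <- matrix(rep(c(1, 0), each = 10), 1, 20,
               dimnames = list("s", LETTERS[1:20]))
  expect_equal(tolerance_scores(m2)$mean, 0.5)
  # mean = sum / 20 whenever all substitutions are present
  set.seed(4)
  m3 <- matrix(runif(60), 3, 20, dimnames = list(paste0("s", 1:3), LETTERS[1:20]))
  t3 <- tolerance_scores(m3)
  expect_equal(t3$mean, t3$sum / 20)
  # excluding the identity substitution drops one cell
  t3x <- tolerance_scores(m3, include_wt = FALSE,
                          wt_aa = c(s1 = "A", s2 = "B", s3 = "C"))
  expect_equal(t3x$n, rep(19L, 3))
})

test_that("specificity censoring is strict, monotone, and antisymmetric in preference", {
  sites <- "s"; subs <- c("v1", "v2", "v3")
  mk <- function(x) matrix(x, 1, 3, dimnames = list(sites, subs))
  mats <- list(X = mk(c(0.20, 0.25, 1.5)),
               Y = mk(c(1.10, 1.00, 0.9)),
               Z = mk(c(1.10, 1.00, 0.9)))
  spec <- specificity_matrix(mats)
  expect_true(spec$censored["s", "v1"])     # 0.20 < 0.25 on X
  expect_false(spec$censored["s", "v2"])    # exactly 0.25 retained
  expect_equal(spec$preferred["s", "v3"], "X")
  expect_true(is.na(spec$preferred["s", "v1"]))
  # antisymmetry of preference ratios on retained variants
  pxy <- preference_score(spec, "X", "Y")
  pyx <- preference_score(spec, "Y", "X")
  keep <- !spec$censored
  expect_equal(unname(pxy[keep] * pyx[keep]), rep(1, sum(keep)))
  # raising the threshold never un-censors
  for (th in c(0.1, 0.25, 0.5, 0.9)) {
    lo <- specificity_matrix(mats, censor_threshold = th)$censored
    hi <- specificity_matrix(mats, censor_threshold = th + 0.05)$censored
    expect_true(all(hi[lo]))
  }
})

test_that("planted screen structure is recovered exactly without noise", {
  truth <- synthetic_screen_truth(seed = 8, substrates = c("X", "Y"), cv = 0,
                                  replicates = 1)
  screen <- simulate_screen(truth)
  mX <- screen_score_matrix(screen, "X")
  expect_equal(unclass(mX)[, colnames(truth$activity[, , "X"])],
               truth$activity[, , "X"], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("tolerant/intolerant sites and substrate preference are recovered at 5% CV", {
  truth <- synthetic_screen_truth(
    seed = 9, sites = paste0("site", 1:5),
    substrates = c("X", "Y", "Z"),
    prefer = c("site3:F" = "X", "site4:M" = "Y"),
    censorable = "site5:C",
    cv = 0.05, replicates = 3)
  screen <- simulate_screen(truth)
  mats <- lapply(c(X = "X", Y = "Y", Z = "Z"),
                 function(b) screen_score_matrix(screen, b))
  tol <- tolerance_scores(mats$X)
  ranked <- tol$site[order(-tol$mean)]
  expect_equal(ranked[1], truth$tolerant)
  expect_equal(ranked[length(ranked)], truth$intolerant)
  spec <- specificity_matrix(mats)
  expect_equal(spec$preferred["site3", "F"], "X")
  expect_equal(spec$preferred["site4", "M"], "Y")
  expect_true(spec$censored["site5", "C"])
})

test_that("4PL fits recover noiseless parameters to within 1%", {
  doses <- 10^seq(0, 4.2, length.out = 8)
  sim <- simulate_dose_response(doses, bottom = 1, top = 7.4, ec50 = 898,
                                hill = 1, cv = 0)
  fit <- fit_dose_response(sim$dose, sim$response)
  expect_true(fit$converged)
  expect_equal(fit$bottom, 1, tolerance = 0.01)
  expect_equal(fit$top, 7.4, tolerance = 0.01)
  expect_equal(fit$ec50, 898, tolerance = 0.01)
  expect_equal(fit$hill, 1, tolerance = 0.01)
  # the fitted curve passes through (EC50, midpoint)
  mid <- fit$bottom + (fit$top - fit$bottom) /
    (1 + 10^((log10(fit$ec50) - log10(fit$ec50)) * fit$hill))
  expect_equal(mid, (fit$bottom + fit$top) / 2)
})

test_that("4PL fits recover EC50 within 15% at 5% CV with 3 replicates", {
  doses <- 10^seq(0, 4.2, length.out = 8)
  sim <- simulate_dose_response(doses, bottom = 1, top = 7.4, ec50 = 898,
                                hill = 1, cv = 0.05, replicates = 3, seed = 12)
  fit <- fit_dose_response(sim$dose, sim$response)
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50 - 898) / 898, 0.15)
  expect_error(fit_dose_response(c(1, 10, 100), c(1, 2, 3)), ">= 4 distinct")
})
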