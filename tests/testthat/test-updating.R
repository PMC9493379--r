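# Calibration-hierarchy fits and likelihood ratio tests.

test_that("intercept update recovers the closed-form shift for constant S", {
  m0 <- ntcp_model(0, c(x = 0))  # S = 0 for everyone

  balanced <- tibble::tibble(x = rnorm(1000), outcome = rep(c(0, 1), 500))
  f <- fit_intercept_update(balanced, m0)
  expect_equal(f$alpha, 0, tolerance = 1e-8)
  expect_equal(f$slope, 1)
  expect_equal(f$n_free_params, 1L)

  skewed <- tibble::tibble(x = rnorm(1000),
                           outcome = c(rep(1, 731), rep(0, 269)))
  f2 <- fit_intercept_update(skewed, m0)
  expect_equal(f2$alpha, qlogis(0.731), tolerance = 1e-6)
  expect_equal(f2$alpha, 1.000, tolerance = 1e-3)
  # the updated model folds alpha into its intercept
  expect_equal(f2$model$intercept, m0$intercept + f2$alpha)
})

test_that("degenerate outcomes are explicit failures", {
  m <- ntcp_model(-1, c(x = 0.5))
  allev <- tibble::tibble(x = rnorm(50), outcome = rep(1, 50))
  expect_error(fit_intercept_update(allev, m), "no non-events")
  expect_error(fit_logistic_recalibration(allev, m), "no non-events")
  expect_error(fit_revision(allev, m), "no non-events")
  noev <- tibble::tibble(x = rnorm(50), outcome = rep(0, 50))
  expect_error(fit_intercept_update(noev, m), "no events")
})

test_that("recalibration matches a dense grid-search MLE on tiny cohorts", {
  m <- ntcp_model(-0.3, c(x = 0.8))
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(15:30, 1)
    d <- tibble::tibble(x = rnorm(n, 0, 2))
    d$outcome <- rbinom(n, 1, plogis(0.4 * linear_predictor(d, m) + 0.2))
    if (all(d$outcome == d$outcome[1])) next
    fit <- tryCatch(
      suppressWarnings(fit_logistic_recalibration(d, m)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next  # separation on tiny n
    if (abs(fit$alpha) > 10 || abs(fit$slope) > 10) next  # near-degenerate MLE
    ref <- oracle_grid_mle(d$outcome, linear_predictor(d, m),
                           a_range = c(-12, 12), b_range = c(-12, 12))
    expect_lt(abs(fit$alpha - ref[["alpha"]]), 1e-4)
    expect_lt(abs(fit$slope - ref[["beta"]]), 1e-4)
  }
})

test_that("recalibration on a constant linear predictor is unidentifiable", {
  m0 <- ntcp_model(0.2, c(x = 0))
  d <- tibble::tibble(x = rnorm(100), outcome = rbinom(100, 1, 0.5))
  expect_error(fit_logistic_recalibration(d, m0), "unidentifiable")
})

test_that("recalibration recovers a known slope distortion", {
  recipe <- cohort_recipe(n = 20000,
                          miscalibration = miscalibration_spec(slope_factor = 0.5),
                          seed = 101)
  cohort <- generate_cohort(recipe)
  fit <- fit_logistic_recalibration(cohort, recipe$truth)
  expect_equal(fit$slope, 0.5, tolerance = 0.08)
})

test_that("revision refits the coefficients and reports standard errors", {
  recipe <- cohort_recipe(n = 20000, seed = 55)
  cohort <- generate_cohort(recipe)
  truth <- recipe$truth
  fit <- fit_revision(cohort, truth)
  expect_equal(fit$n_free_params, 7L)
  est <- c(fit$model$intercept, fit$model$coefficients)
  tru <- c(truth$intercept, truth$coefficients)
  expect_true(all(abs(est - tru) <= 4 * fit$std_errors))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 7)
})

test_that("revision fails loudly on collinearity and separation", {
  m <- ntcp_model(-1, c(x = 0.5, z = 0.2))
  set.seed(9)
  d <- tibble::tibble(x = rnorm(200))
  d$z <- 2 * d$x  # exact duplicate direction
  d$outcome <- rbinom(200, 1, plogis(-1 + 0.5 * d$x))
  expect_error(fit_revision(d, m), "rank deficient")

  d2 <- tibble::tibble(x = c(rnorm(30, -4), rnorm(30, 4)), z = rnorm(60))
  d2$outcome <- as.integer(d2$x > 0)  # perfectly separated by x
  expect_error(fit_revision(d2, m), "separation|converge")
})

test_that("likelihood ratio tests match chi-square hand arithmetic", {
  mk <- function(level, ll, k) {
    ntcpval:::new_update_fit(level, 0, 1, ntcp_model(0, c(x = 0)),
                             log_lik = ll, n_free_params = k,
                             n = 100, n_events = 40)
  }
  same <- lr_test(mk("original", -100, 0), mk("revision", -100, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  t6 <- lr_test(mk("original", -100, 0), mk("revision", -97, 2))
  expect_equal(t6$statistic, 6)
  expect_equal(t6$df, 2L)
  expect_equal(t6$p_value, exp(-3), tolerance = 1e-12)

  expect_error(lr_test(mk("revision", -97, 2), mk("original", -100, 0)),
               "not nested")
  # tiny optimizer-noise reversal floors silently; a gross one warns
  expect_silent(lr_test(mk("original", -100 + 1e-9, 0), mk("revision", -100, 2)))
  expect_warning(lr_test(mk("original", -99, 0), mk("revision", -99.5, 2)),
                 "floored")
})

test_that("log-likelihood is non-decreasing over the nested hierarchy", {
  m <- nipp_dysphagia_model()
  for (seed in c(11, 12, 13)) {
    cohort <- generate_cohort(cohort_recipe(
      n = 400, seed = seed,
      miscalibration = miscalibration_spec(delta_intercept = runif(1, -1, 1))))
    res <- ctp_select(cohort, m)
    lls <- vapply(res$fits, `[[`, numeric(1), "log_lik")
    expect_true(all(diff(lls) >= -1e-6))
  }
})

test_that("re-recalibrating an updated model returns the identity", {
  recipe <- cohort_recipe(
    n = 3000, seed = 77,
    miscalibration = miscalibration_spec(delta_intercept = 0.8,
                                         slope_factor = 0.7))
  cohort <- generate_cohort(recipe)
  fit <- fit_logistic_recalibration(cohort, recipe$truth)
  refit <- fit_logistic_recalibration(cohort, fit$model)
  expect_equal(refit$alpha, 0, tolerance = 1e-6)
  expect_equal(refit$slope, 1, tolerance = 1e-6)
})
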