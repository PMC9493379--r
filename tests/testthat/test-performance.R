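# Discrimination and calibration metrics.

test_that("AUC equals exhaustive pair enumeration, including ties", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  expect_error(auc(rep(1, 5), runif(5)), "single-class")

  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (all(y == y[1])) y[sample(n, 1)] <- 1 - y[1]
    # coarse grid of values forces plenty of ties
    p <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_identical(auc(y, p), oracle_auc(y, p))
  }
})

test_that("AUC confidence intervals behave like intervals", {
  set.seed(7)
  y <- rbinom(200, 1, 0.4)
  p <- plogis(qlogis(0.4) + 1.2 * y + rnorm(200))
  ci <- auc_ci(y, p)
  a <- auc(y, p)
  expect_lte(ci[["low"]], a)
  expect_gte(ci[["high"]], a)
  expect_gte(ci[["low"]], 0)
  expect_lte(ci[["high"]], 1)

  bci <- auc_ci(y, p, method = "bootstrap", boot_n = 200, seed = 9)
  expect_lt(bci[["low"]], bci[["high"]])
  expect_equal(bci, auc_ci(y, p, method = "bootstrap", boot_n = 200, seed = 9))
})

test_that("AUC interval width shrinks like 1/sqrt(n)", {
  widths <- function(n, reps = 30) {
    vapply(seq_len(reps), function(i) {
      set.seed(1000 + i)
      y <- rbinom(n, 1, 0.4)
      if (all(y == y[1])) y[1] <- 1 - y[1]
      p <- plogis(-0.4 + 1.5 * y + rnorm(n))
      ci <- auc_ci(y, p)
      ci[["high"]] - ci[["low"]]
    }, numeric(1))
  }
  ratio <- mean(widths(800)) / mean(widths(200))
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.65)
})

test_that("all-tied predictions collapse the DeLong interval at 0.5", {
  y <- rep(c(0, 1), 8)
  p <- rep(0.3, 16)
  ci <- suppressWarnings(auc_ci(y, p))
  expect_equal(unname(ci), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("sensitivity and specificity match the confusion table", {
  expect_equal(unname(sens_spec(c(0, 1), c(0.4, 0.6))[1:2]), c(1, 1))
  expect_equal(unname(sens_spec(c(0, 1), c(0.6, 0.4))[1:2]), c(0, 0))
  ss <- sens_spec(c(0, 0, 1, 1), c(0.2, 0.55, 0.45, 0.9), threshold = 0.5)
  expect_equal(unname(ss[1:2]), c(0.5, 0.5))
  expect_warning(out <- sens_spec(rep(1, 4), runif(4)), "undefined")
  expect_true(is.na(out[["specificity"]]))

  yj <- c(0, 0, 0, 1, 1, 1)
  pj <- c(0.1, 0.2, 0.3, 0.6, 0.7, 0.8)
  ssy <- sens_spec(yj, pj, threshold = "youden")
  expect_equal(unname(ssy[1:2]), c(1, 1))
})

test_that("Brier score matches hand arithmetic and its decomposition", {
  expect_equal(brier_score(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(brier_score(rbinom(50, 1, 0.5), rep(0.5, 50)), 0.25)
  expect_equal(brier_score(c(0, 1), c(0.2, 0.8)), 0.04, tolerance = 1e-12)

  # grouped constant predictions: Brier = calibration + refinement
  p_g <- c(0.2, 0.6)
  n_g <- c(40, 60)
  o_g <- c(0.25, 0.5)  # observed event rates per group
  y <- c(rep(1, 10), rep(0, 30), rep(1, 30), rep(0, 30))
  p <- c(rep(0.2, 40), rep(0.6, 60))
  w <- n_g / sum(n_g)
  calib <- sum(w * (p_g - o_g)^2)
  refine <- sum(w * o_g * (1 - o_g))
  expect_equal(brier_score(y, p), calib + refine, tolerance = 1e-12)
})

test_that("Hosmer-Lemeshow matches the grouped hand computation", {
  # two groups of 10: mean p 0.2 with 4 events, mean p 0.5 with 5 events
  y <- c(rep(1, 4), rep(0, 6), rep(1, 5), rep(0, 5))
  p <- c(rep(0.2, 10), rep(0.5, 10))
  hl <- hosmer_lemeshow(y, p, g = 2, df_offset = 0)
  expect_equal(hl$statistic, 2.5, tolerance = 1e-6)
  expect_equal(hl$df, 2L)

  # perfectly calibrated groups give a zero statistic
  y0 <- c(rep(1, 2), rep(0, 8), rep(1, 5), rep(0, 5))
  hl0 <- hosmer_lemeshow(y0, p, g = 2)
  expect_equal(hl0$statistic, 0, tolerance = 1e-12)
  expect_equal(hl0$p_value, 1)

  expect_error(hosmer_lemeshow(c(0, 1, 1), c(0.2, 0.4, 0.6), g = 10),
               "fewer observations")
})

test_that("Hosmer-Lemeshow is invariant to within-group permutations", {
  set.seed(3)
  p <- runif(200)
  y <- rbinom(200, 1, p)
  base <- hosmer_lemeshow(y, p)
  grp <- cut(p, stats::quantile(p, seq(0, 1, 0.1)), include.lowest = TRUE,
             labels = FALSE)
  idx <- seq_along(p)
  for (g in unique(grp)) idx[grp == g] <- sample(idx[grp == g])
  perm <- hosmer_lemeshow(y[idx], p[idx])
  expect_equal(perm$statistic, base$statistic, tolerance = 1e-12)
})

test_that("HL p-values are near-uniform under the correct model", {
  # externally specified probabilities: the statistic is compared to
  # chi-square with g (not g - 2) degrees of freedom
  set.seed(12)
  p <- plogis(rnorm(1000, -0.5, 1.2))
  pvals <- vapply(1:200, function(i) {
    y <- rbinom(length(p), 1, p)
    hosmer_lemeshow(y, p, g = 10, df_offset = 0)$p_value
  }, numeric(1))
  ks <- max(abs(sort(pvals) - (seq_along(pvals) - 0.5) / length(pvals)))
  expect_lt(ks, 0.1)
})

test_that("calibration curves track gross miscalibration and refuse junk", {
  set.seed(8)
  p <- runif(3000, 0.05, 0.95)
  y_inv <- rbinom(3000, 1, 1 - p)  # outcome-inverted sample
  cv <- calibration_curve(y_inv, p)
  hi <- cv$p > 0.55
  expect_true(all(cv$c_hat[hi] < cv$p[hi]))

  expect_error(calibration_curve(c(0, 1, 1, 0, 1), runif(5)), "at least 20")
  expect_error(calibration_curve(rbinom(50, 1, 0.3), rep(0.3, 50)),
               "constant")
})

test_that("E statistics match the linear-interpolation quantile by hand", {
  ident <- tibble::tibble(p = seq(0, 1, length.out = 11),
                          c_hat = seq(0, 1, length.out = 11))
  expect_equal(unname(e_statistics(ident, c(0.1, 0.5, 0.9))), c(0, 0, 0))

  curve <- tibble::tibble(p = c(0.2, 0.4, 0.6), c_hat = c(0.3, 0.6, 0.9))
  es <- e_statistics(curve, c(0.2, 0.4, 0.6))
  expect_equal(es[["emax"]], 0.3, tolerance = 1e-12)
  expect_equal(es[["eavg"]], 0.2, tolerance = 1e-12)
  expect_equal(es[["e90"]], 0.28, tolerance = 1e-12)

  set.seed(13)
  for (i in 1:10) {
    p <- runif(50)
    cv <- tibble::tibble(p = sort(runif(20)), c_hat = runif(20))
    es <- suppressWarnings(e_statistics(cv, p))
    expect_lte(es[["eavg"]], es[["e90"]] + 1e-12)
    expect_lte(es[["e90"]], es[["emax"]] + 1e-12)
  }
})

test_that("the validation report assembles all four levels deterministically", {
  cohort <- generate_cohort(cohort_recipe(n = 277, seed = 19))
  cfg <- run_config(seed = 19)
  rep1 <- validation_report(cohort, nipp_dysphagia_model(), cfg)
  expect_named(rep1$levels, c("original", "intercept_update",
                              "logistic_recalibration", "revision"))
  td <- tidy(rep1)
  expect_equal(nrow(td), 4)
  expect_true(all(c("auc", "brier", "emax", "hl_statistic") %in% names(td)))
  expect_equal(sum(td$selected), 1)

  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_report(rep1, f1)
  write_report(validation_report(cohort, nipp_dysphagia_model(), cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  pl <- autoplot(rep1)
  expect_s3_class(pl, "ggplot")
  expect_s3_class(plot_roc(rep1), "ggplot")
  expect_s3_class(autoplot(rep1$levels$original$curve), "ggplot")
})
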