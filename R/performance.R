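# Discrimination and calibration metrics for externally validated
# probability predictions.

check_binary_mix <- function(y) {
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1", call. = FALSE)
  if (all(y == 1) || all(y == 0)) {
    stop("discrimination is undefined on a single-class outcome", call. = FALSE)
  }
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance: the probability that a randomly chosen event
#' receives a higher prediction than a randomly chosen non-event, with
#' ties counted one half. Computed from midranks, which is exactly the
#' all-pairs enumeration.
#'
#' @param y Binary outcome vector (0/1).
#' @param p Predicted probabilities (any monotone score works).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
#' @export
auc <- function(y, p) {
  stopifnot(length(y) == length(p))
  check_binary_mix(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confidence interval for the AUC
#'
#' DeLong variance-based interval by default, or a seeded stratified
#' bootstrap; either way truncated to `[0, 1]`.
#'
#' @inheritParams auc
#' @param level Confidence level, default 0.95.
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param boot_n Bootstrap resamples (bootstrap method only).
#' @param seed Seed for the bootstrap resamples.
#' @return Named numeric vector `c(low, high)`.
#' @export
auc_ci <- function(y, p, level = 0.95, method = c("delong", "bootstrap"),
                   boot_n = 2000, seed = 1L) {
  method <- match.arg(method)
  check_binary_mix(y)
  roc <- pROC::roc(response = factor(y, levels = c(0, 1)), predictor = p,
                   direction = "<", quiet = TRUE)
  ci <- if (method == "delong") {
    pROC::ci.auc(roc, conf.level = level, method = "delong")
  } else {
    set.seed(seed)
    pROC::ci.auc(roc, conf.level = level, method = "bootstrap",
                 boot.n = boot_n)
  }
  c(low = max(0, as.numeric(ci[1])), high = min(1, as.numeric(ci[3])))
}

#' Sensitivity and specificity at a probability threshold
#'
#' Classifies `p >= threshold` as predicted positive.
#'
#' @inheritParams auc
#' @param threshold Classification threshold in (0, 1), or `"youden"` for
#'   the threshold maximizing sensitivity + specificity - 1 over the
#'   observed predictions.
#' @return Named vector `c(sensitivity, specificity, threshold)`.
#' @export
sens_spec <- function(y, p, threshold = 0.5) {
  stopifnot(length(y) == length(p))
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1", call. = FALSE)
  if (identical(threshold, "youden")) threshold <- youden_threshold(y, p)
  stopifnot(is.numeric(threshold), threshold > 0, threshold < 1)
  pos <- p >= threshold
  tp <- sum(pos & y == 1); fn <- sum(!pos & y == 1)
  tn <- sum(!pos & y == 0); fp <- sum(pos & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (is.na(sens) || is.na(spec)) {
    warning("single-class outcome: ",
            if (is.na(sens)) "sensitivity" else "specificity",
            " is undefined", call. = FALSE)
  }
  c(sensitivity = sens, specificity = spec, threshold = threshold)
}

# Youden-optimal threshold over candidate cut points (midpoints between
# adjacent distinct predictions).
youden_threshold <- function(y, p) {
  check_binary_mix(y)
  ps <- sort(unique(p))
  cand <- if (length(ps) > 1) (ps[-1] + ps[-length(ps)]) / 2 else ps
  cand <- pmin(pmax(cand, 1e-9), 1 - 1e-9)
  j <- vapply(cand, function(t) {
    s <- sum(p >= t & y == 1) / sum(y == 1)
    sp <- sum(p < t & y == 0) / sum(y == 0)
    s + sp - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; 0 is perfect, lower is better.
#'
#' @inheritParams auc
#' @return A number in `[0, 1]`.
#' @export
brier_score <- function(y, p) {
  stopifnot(length(y) == length(p), length(y) > 0)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1", call. = FALSE)
  mean((p - y)^2)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Patients are grouped into `g` quantile bins of predicted probability;
#' within each bin observed events `O` are compared with expected events
#' `E = sum(p)` via
#' `X2 = sum((O - E)^2 / E + ((n - O) - (n - E))^2 / (n - E))`, referred
#' to a chi-square with `g - df_offset` degrees of freedom. The default
#' offset 2 is the convention for probabilities fitted on the same data;
#' use `df_offset = 0` when the probabilities are externally specified,
#' as in external validation.
#'
#' A bin whose expected events (or non-events) are zero is merged with
#' its neighbour, with a warning.
#'
#' @inheritParams auc
#' @param g Number of quantile groups (default 10).
#' @param df_offset Subtracted from the group count to give the degrees
#'   of freedom (default 2).
#' @return A list: `statistic`, `df`, `p_value`, `g_used`, and the
#'   per-group table `groups` (tibble: n, observed, expected, mean_p).
#' @export
hosmer_lemeshow <- function(y, p, g = 10, df_offset = 2) {
  stopifnot(length(y) == length(p))
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1", call. = FALSE)
  g <- as.integer(g)
  if (g < 2) stop("`g` must be at least 2", call. = FALSE)
  if (length(y) < g) stop("fewer observations (", length(y),
                          ") than groups (", g, ")", call. = FALSE)
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = g + 1),
                               names = FALSE, type = 7))
  if (length(br) < 3) stop("predictions are too heavily tied to form ",
                           "at least 2 groups", call. = FALSE)
  grp <- cut(p, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- tibble::tibble(
    group = sort(unique(grp)),
    n = as.numeric(tapply(y, grp, length)),
    observed = as.numeric(tapply(y, grp, sum)),
    expected = as.numeric(tapply(p, grp, sum)),
    mean_p = as.numeric(tapply(p, grp, mean))
  )
  # merge degenerate bins (expected events or non-events exactly 0)
  repeat {
    bad <- which(tab$expected == 0 | tab$expected == tab$n)
    if (length(bad) == 0 || nrow(tab) <= 2) break
    i <- bad[1]
    j <- if (i == 1) 2L else i - 1L
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab$mean_p[j] <- tab$expected[j] / tab$n[j]
    tab <- tab[-i, ]
    warning("Hosmer-Lemeshow group with degenerate expected count merged ",
            "with its neighbour", call. = FALSE)
  }
  O <- tab$observed; E <- tab$expected; n <- tab$n
  x2 <- sum((O - E)^2 / E + ((n - O) - (n - E))^2 / (n - E))
  df <- max(1L, nrow(tab) - as.integer(df_offset))
  list(statistic = x2, df = df,
       p_value = stats::pchisq(x2, df, lower.tail = FALSE),
       g_used = nrow(tab), groups = tab)
}

#' Flexible calibration curve
#'
#' Locally weighted (lowess, local linear, no robustness iterations)
#' regression of the binary outcome on the predicted probability,
#' evaluated on an evenly spaced grid spanning the observed prediction
#' range and truncated to `[0, 1]`. On a calibrated model the curve lies
#' on the diagonal.
#'
#' @inheritParams auc
#' @param span Smoother span (fraction of points in each local fit),
#'   default 0.75.
#' @param grid_n Number of grid points, default 101.
#' @param min_n Minimum number of observations (default 20); fewer is an
#'   error, since a smoothed curve on a handful of binary points is
#'   meaningless.
#' @return A `calibration_curve`: tibble with columns `p` (predicted) and
#'   `c_hat` (smoothed observed proportion), with the smoother settings
#'   as attributes.
#' @export
calibration_curve <- function(y, p, span = 0.75, grid_n = 101, min_n = 20) {
  stopifnot(length(y) == length(p))
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1", call. = FALSE)
  if (length(y) < min_n) {
    stop("at least ", min_n, " observations are needed for a flexible ",
         "calibration curve; consider grouped observed proportions instead",
         call. = FALSE)
  }
  if (diff(range(p)) < sqrt(.Machine$double.eps)) {
    stop("predictions are constant: no calibration curve is definable",
         call. = FALSE)
  }
  fit <- stats::lowess(p, y, f = span, iter = 0)
  grid <- seq(min(p), max(p), length.out = grid_n)
  c_hat <- stats::approx(fit$x, fit$y, xout = grid, ties = "ordered",
                         rule = 2)$y
  out <- tibble::tibble(p = grid, c_hat = pmin(pmax(c_hat, 0), 1))
  attr(out, "smoother") <- "lowess"
  attr(out, "span") <- span
  class(out) <- c("calibration_curve", class(out))
  out
}

#' Calibration error statistics from a flexible calibration curve
#'
#' For each patient the absolute difference between the predicted
#' probability and the curve's calibrated estimate,
#' `d_i = |p_i - c_hat(p_i)|` (curve linearly interpolated), is computed;
#' Emax is the maximum, Eavg the mean and E90 the 90th percentile
#' (linear-interpolation quantile) of the `d_i`.
#'
#' @param curve A [calibration_curve()] (or any data frame with columns
#'   `p` and `c_hat`).
#' @param p Predicted probabilities for the patients being summarized.
#' @return Named vector `c(emax, eavg, e90)`.
#' @export
e_statistics <- function(curve, p) {
  stopifnot(is.data.frame(curve), all(c("p", "c_hat") %in% names(curve)),
            length(p) > 0)
  if (any(p < min(curve$p) - 1e-12 | p > max(curve$p) + 1e-12)) {
    warning("predictions outside the calibration-curve grid; ",
            "nearest-endpoint extrapolation used", call. = FALSE)
  }
  c_hat <- stats::approx(curve$p, curve$c_hat, xout = p, rule = 2,
                         ties = "ordered")$y
  d <- abs(p - c_hat)
  c(emax = max(d), eavg = mean(d),
    e90 = unname(stats::quantile(d, 0.9, type = 7)))
}

#' Plot a flexible calibration curve
#'
#' @param object A [calibration_curve()].
#' @param ... Unused.
#' @return A ggplot: the curve against the ideal diagonal.
#' @importFrom ggplot2 autoplot
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p, y = .data$c_hat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166AC") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted probability",
                  y = "Observed proportion (smoothed)",
                  title = "Flexible calibration curve") +
    ggplot2::theme_minimal()
}
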