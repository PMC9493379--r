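# The four-level calibration hierarchy: original model, re-calibration in
# the large, logistic recalibration, and full model revision. All refits
# are Bernoulli maximum likelihood via IRLS (stats::glm), with the original
# linear predictor entering as an offset or covariate.

ctp_levels <- c("original", "intercept_update", "logistic_recalibration", "revision")

glm_ctrl <- function() stats::glm.control(epsilon = 1e-8, maxit = 100)

check_outcome_mix <- function(y, level) {
  if (all(y == 1) || all(y == 0)) {
    stop("cannot fit '", level, "': cohort has no ",
         if (all(y == 1)) "non-events" else "events",
         " so the maximum likelihood estimate is not finite", call. = FALSE)
  }
}

new_update_fit <- function(level, alpha, slope, model, log_lik, n_free_params,
                           n, n_events, converged = TRUE, std_errors = NULL) {
  structure(
    list(level = level, alpha = alpha, slope = slope, model = model,
         log_lik = log_lik, n_free_params = as.integer(n_free_params),
         n = as.integer(n), n_events = as.integer(n_events),
         converged = converged, std_errors = std_errors),
    class = "ntcp_update"
  )
}

#' @export
print.ntcp_update <- function(x, ...) {
  cat("<ntcp_update> level: ", x$level, "\n", sep = "")
  cat("  calibration intercept: ", format(x$alpha),
      "   slope: ", format(x$slope), "\n", sep = "")
  cat("  log-likelihood: ", format(x$log_lik),
      "   free parameters: ", x$n_free_params, "\n", sep = "")
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' Tidy / glance methods for calibration-hierarchy fits
#'
#' `tidy()` returns the updated model's terms; `glance()` returns the
#' one-row fit summary (calibration intercept and slope, log-likelihood,
#' free parameters, convergence).
#'
#' @param x An `ntcp_update` fit.
#' @param ... Unused.
#' @method tidy ntcp_update
#' @export
tidy.ntcp_update <- function(x, ...) {
  out <- tidy(x$model)
  if (!is.null(x$std_errors)) out$std_error <- unname(x$std_errors)
  out
}

#' @rdname tidy.ntcp_update
#' @importFrom generics glance
#' @method glance ntcp_update
#' @export
glance.ntcp_update <- function(x, ...) {
  tibble::tibble(level = x$level, alpha = x$alpha, slope = x$slope,
                 log_lik = x$log_lik, n_free_params = x$n_free_params,
                 n = x$n, n_events = x$n_events, converged = x$converged)
}

#' Evaluate the original model without refitting
#'
#' Level 1 of the calibration hierarchy: the model is applied as printed
#' (calibration intercept fixed at 0, slope fixed at 1, no free
#' parameters) and its Bernoulli log-likelihood on the cohort is recorded.
#'
#' @param data Cohort table with outcome column `outcome`.
#' @param model An [ntcp_model()].
#' @return An `ntcp_update` with `level = "original"`.
#' @export
fit_original <- function(data, model) {
  pred <- predict_ntcp(data, model)
  ll <- log_likelihood(pred$outcome, pred$.ntcp)
  new_update_fit("original", alpha = 0, slope = 1, model = model,
                 log_lik = ll, n_free_params = 0L, n = nrow(data),
                 n_events = sum(pred$outcome))
}

#' Re-calibration in the large
#'
#' Level 2: the original linear predictor S enters as a fixed offset
#' (slope pinned at 1) and only a new intercept alpha is estimated by
#' maximum likelihood, correcting the overall event rate.
#'
#' @inheritParams fit_original
#' @return An `ntcp_update` with `level = "intercept_update"`; the updated
#'   model is the original with `alpha` added to its intercept.
#' @export
fit_intercept_update <- function(data, model) {
  pred <- predict_ntcp(data, model)
  y <- pred$outcome
  check_outcome_mix(y, "intercept_update")
  S <- pred$.lp
  fit <- stats::glm(y ~ 1, family = stats::binomial(), offset = S,
                    control = glm_ctrl())
  alpha <- unname(stats::coef(fit)[1])
  upd <- ntcp_model(model$intercept + alpha, model$coefficients,
                    name = paste0(model$name, " + intercept update"),
                    coding = model$coding)
  new_update_fit("intercept_update", alpha = alpha, slope = 1, model = upd,
                 log_lik = as.numeric(stats::logLik(fit)),
                 n_free_params = 1L, n = nrow(data), n_events = sum(y),
                 converged = fit$converged)
}

#' Logistic recalibration
#'
#' Level 3: intercept alpha and one overall slope beta_cal on the original
#' linear predictor are estimated jointly, so the updated probability is
#' `plogis(alpha + beta_cal * S)`. (alpha, beta_cal) = (0, 1) means the
#' model is already calibrated.
#'
#' @inheritParams fit_original
#' @return An `ntcp_update` with `level = "logistic_recalibration"`.
#' @export
fit_logistic_recalibration <- function(data, model) {
  pred <- predict_ntcp(data, model)
  y <- pred$outcome
  check_outcome_mix(y, "logistic_recalibration")
  S <- pred$.lp
  if (stats::sd(S) < sqrt(.Machine$double.eps)) {
    stop("cannot fit 'logistic_recalibration': the linear predictor is ",
         "constant across patients, so the slope is unidentifiable",
         call. = FALSE)
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ S, family = stats::binomial(), control = glm_ctrl()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  converged <- fit$converged && !sep
  if (!converged) {
    warning("logistic recalibration did not converge cleanly ",
            "(possible separation along the linear predictor); ",
            "estimates are reported but flagged", call. = FALSE)
  }
  cf <- stats::coef(fit)
  alpha <- unname(cf[1]); slope <- unname(cf[2])
  upd <- ntcp_model(slope * model$intercept + alpha,
                    slope * model$coefficients,
                    name = paste0(model$name, " + logistic recalibration"),
                    coding = model$coding)
  new_update_fit("logistic_recalibration", alpha = alpha, slope = slope,
                 model = upd, log_lik = as.numeric(stats::logLik(fit)),
                 n_free_params = 2L, n = nrow(data), n_events = sum(y),
                 converged = converged)
}

#' Model revision
#'
#' Level 4: the full predictor set of the original model is refit on the
#' validation cohort, re-estimating the intercept and every coefficient.
#'
#' @inheritParams fit_original
#' @param predictors Predictor columns to refit; defaults to the model's
#'   coefficient names.
#' @return An `ntcp_update` with `level = "revision"`; `$model` holds the
#'   revised model and `$std_errors` the estimated standard errors
#'   (intercept first).
#' @export
fit_revision <- function(data, model, predictors = names(model$coefficients)) {
  if (!"outcome" %in% names(data)) {
    stop("cohort is missing the 'outcome' column", call. = FALSE)
  }
  y <- data$outcome
  if (!all(y %in% c(0, 1))) stop("'outcome' must be binary 0/1", call. = FALSE)
  check_outcome_mix(y, "revision")
  X <- predictor_matrix(data, ntcp_model(0, stats::setNames(rep(0, length(predictors)),
                                                            predictors)),
                        dose_ceiling = NULL)
  A <- cbind(`(Intercept)` = 1, X)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    aliased <- colnames(A)[qrA$pivot[(qrA$rank + 1L):ncol(A)]]
    stop("design matrix is rank deficient; offending predictor(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(y = y, X, check.names = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = df,
               control = glm_ctrl()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep || !fit$converged) {
    cf <- stats::coef(fit)[-1]
    sds <- apply(X, 2, stats::sd)
    worst <- names(which.max(abs(cf) * ifelse(sds > 0, sds, 1)))
    stop("revision fit shows (quasi-)separation or non-convergence; ",
         "most extreme predictor: ", worst, call. = FALSE)
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  revised <- ntcp_model(unname(cf[1]),
                        stats::setNames(unname(cf[-1]), predictors),
                        name = paste0(model$name, " (revised)"),
                        coding = model$coding)
  new_update_fit("revision", alpha = NA_real_, slope = NA_real_,
                 model = revised, log_lik = as.numeric(stats::logLik(fit)),
                 n_free_params = length(predictors) + 1L, n = nrow(data),
                 n_events = sum(y), converged = TRUE, std_errors = se)
}

#' Likelihood ratio test between nested calibration levels
#'
#' `statistic = 2 * (logLik_complex - logLik_simple)`, floored at zero if
#' optimizer noise makes it marginally negative, referred to the upper
#' tail of a chi-square with df equal to the difference in free
#' parameters.
#'
#' @param simple,complex `ntcp_update` fits on the same cohort, with
#'   `simple` nested in `complex`.
#' @return One-row tibble: `simple`, `complex`, `statistic`, `df`,
#'   `p_value`.
#' @export
lr_test <- function(simple, complex) {
  stopifnot(inherits(simple, "ntcp_update"), inherits(complex, "ntcp_update"))
  if (simple$n != complex$n) {
    stop("fits being compared were not made on the same cohort", call. = FALSE)
  }
  if (complex$n_free_params <= simple$n_free_params ||
      match(simple$level, ctp_levels) >= match(complex$level, ctp_levels)) {
    stop("'", simple$level, "' is not nested in '", complex$level, "'",
         call. = FALSE)
  }
  stat <- 2 * (complex$log_lik - simple$log_lik)
  if (stat < 0) {
    if (stat < -1e-6) {
      warning("likelihood ratio statistic negative beyond optimizer ",
              "tolerance (", format(stat), "); floored at 0", call. = FALSE)
    }
    stat <- 0
  }
  df <- complex$n_free_params - simple$n_free_params
  tibble::tibble(simple = simple$level, complex = complex$level,
                 statistic = stat, df = as.integer(df),
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
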