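# Synthetic cohort generation.
#
# Doses are drawn from a Gaussian copula: a latent multivariate normal
# with exchangeable correlation rho supplies the dependence, and each
# margin is mapped through its doubly-truncated-normal quantile function,
# so every dose marginal is exactly the configured normal truncated to
# [0, ceiling] and negative doses are impossible by construction. Draw
# order within a seed is fixed (modality, latent dose normals, tumour
# location, baseline dysphagia, outcome), which pins byte-level
# reproducibility.

#' Miscalibration specification
#'
#' Describes how the data-generating outcome law departs from a truth
#' model: the outcome probability is
#' `plogis(slope_factor * S_truth + delta_intercept)` where `S_truth` is
#' the truth model's linear predictor after any coefficient overrides.
#' The three knobs mirror the three departures the calibration hierarchy
#' corrects: an intercept shift (fixed by re-calibration in the large), a
#' slope distortion (fixed by logistic recalibration), and changed
#' coefficients (fixed only by revision).
#'
#' @param delta_intercept Log-odds shift added to the linear predictor.
#' @param slope_factor Positive multiplier on the linear predictor.
#' @param coefficient_overrides Named list/vector replacing individual
#'   truth-model coefficients before the slope/shift are applied to the
#'   generated outcome law.
#' @return A list of class `miscalibration_spec`.
#' @export
miscalibration_spec <- function(delta_intercept = 0, slope_factor = 1,
                                coefficient_overrides = NULL) {
  stopifnot(is.numeric(delta_intercept), length(delta_intercept) == 1,
            is.finite(delta_intercept),
            is.numeric(slope_factor), length(slope_factor) == 1,
            is.finite(slope_factor), slope_factor > 0)
  if (!is.null(coefficient_overrides)) {
    coefficient_overrides <- unlist(coefficient_overrides)
    if (length(coefficient_overrides) == 0L) coefficient_overrides <- NULL
  }
  if (!is.null(coefficient_overrides)) {
    if (is.null(names(coefficient_overrides)) ||
        any(!nzchar(names(coefficient_overrides)))) {
      stop("`coefficient_overrides` must be named", call. = FALSE)
    }
  }
  structure(list(delta_intercept = delta_intercept,
                 slope_factor = slope_factor,
                 coefficient_overrides = coefficient_overrides),
            class = "miscalibration_spec")
}

#' Apply a miscalibration spec to a model
#'
#' Returns the model actually generating outcomes under the spec:
#' coefficients are scaled by `slope_factor`, the intercept becomes
#' `slope_factor * intercept + delta_intercept`, and coefficient
#' overrides are applied last (an override therefore sets the final
#' coefficient value).
#'
#' @param model An [ntcp_model()].
#' @param spec A [miscalibration_spec()].
#' @return A miscalibrated [ntcp_model()].
#' @export
apply_miscalibration <- function(model, spec) {
  stopifnot(inherits(model, "ntcp_model"), inherits(spec, "miscalibration_spec"))
  co <- spec$coefficient_overrides
  if (!is.null(co)) {
    unknown <- setdiff(names(co), names(model$coefficients))
    if (length(unknown) > 0L) {
      stop("coefficient override(s) for unknown predictor(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  coefs <- model$coefficients * spec$slope_factor
  intercept <- model$intercept * spec$slope_factor + spec$delta_intercept
  if (!is.null(co)) coefs[names(co)] <- co
  ntcp_model(intercept, coefs,
             name = paste0(model$name, " (miscalibrated)"),
             coding = model$coding)
}

#' Default per-modality dose marginals (Gy)
#'
#' Mean and SD of the mean dose to each organ at risk, by treatment arm,
#' for a 277-patient head-and-neck (chemo)radiotherapy validation cohort:
#' photon arm oral cavity 33.2 (15.4), PCM superior 55.5 (17.7), PCM
#' medium 50.2 (17.4), PCM inferior 38.2 (19.9); proton arm 24.1 (11.9),
#' 35.1 (8.3), 41.2 (12.6), 37.5 (17.9). Photon and photon-chemo patients
#' share the photon marginals.
#'
#' @return Nested list: arm -> predictor -> c(mean, sd).
#' @export
default_dose_marginals <- function() {
  list(
    photon = list(dmean_oral_cavity  = c(mean = 33.2, sd = 15.4),
                  dmean_pcm_superior = c(mean = 55.5, sd = 17.7),
                  dmean_pcm_medium   = c(mean = 50.2, sd = 17.4),
                  dmean_pcm_inferior = c(mean = 38.2, sd = 19.9)),
    proton = list(dmean_oral_cavity  = c(mean = 24.1, sd = 11.9),
                  dmean_pcm_superior = c(mean = 35.1, sd = 8.3),
                  dmean_pcm_medium   = c(mean = 41.2, sd = 12.6),
                  dmean_pcm_inferior = c(mean = 37.5, sd = 17.9))
  )
}

#' Cohort recipe
#'
#' Generative parameters for a synthetic validation cohort. Defaults
#' emulate the 277-patient cohort: modality mix 204/59/14
#' (photon / photon + chemotherapy / proton), the per-arm dose marginals
#' of [default_dose_marginals()], 68% pharyngeal tumours, 15% baseline
#' dysphagia, truth model = the packaged original dysphagia model, no
#' miscalibration.
#'
#' @param n Cohort size.
#' @param modality_mix Named proportions over
#'   `photon`/`photon_chemo`/`proton`; normalized to sum 1.
#' @param dose_marginals Per-arm marginals as in
#'   [default_dose_marginals()].
#' @param dose_correlation Exchangeable latent correlation among the four
#'   doses, in `[0, 0.95]` (default 0.4).
#' @param p_pharynx Prevalence of pharyngeal tumour location.
#' @param p_baseline_dysphagia Prevalence of baseline grade >= 2
#'   dysphagia (0.15 default; the development cohort's 0.25 is a useful
#'   preset for case-mix-shift experiments).
#' @param truth Truth [ntcp_model()] generating outcomes (default: the
#'   packaged original model).
#' @param miscalibration A [miscalibration_spec()].
#' @param dose_ceiling Upper truncation bound in Gy (default 80).
#' @param seed Integer master seed.
#' @return A list of class `cohort_recipe`.
#' @export
cohort_recipe <- function(n = 277,
                          modality_mix = c(photon = 204, photon_chemo = 59,
                                           proton = 14),
                          dose_marginals = default_dose_marginals(),
                          dose_correlation = 0.4,
                          p_pharynx = 0.68,
                          p_baseline_dysphagia = 0.15,
                          truth = nipp_dysphagia_model(),
                          miscalibration = miscalibration_spec(),
                          dose_ceiling = 80,
                          seed = 1L) {
  stopifnot(n >= 1, all(modality_mix >= 0), sum(modality_mix) > 0,
            dose_correlation >= 0, dose_correlation <= 0.95,
            p_pharynx > 0, p_pharynx < 1,
            p_baseline_dysphagia > 0, p_baseline_dysphagia < 1,
            inherits(truth, "ntcp_model"),
            inherits(miscalibration, "miscalibration_spec"),
            dose_ceiling > 0)
  if (!setequal(names(modality_mix), c("photon", "photon_chemo", "proton"))) {
    stop("`modality_mix` must be named photon/photon_chemo/proton",
         call. = FALSE)
  }
  for (arm in names(dose_marginals)) {
    for (oar in names(dose_marginals[[arm]])) {
      m <- dose_marginals[[arm]][[oar]]
      if (!is.numeric(m) || m[["sd"]] <= 0) {
        stop("infeasible dose marginal (sd <= 0) for ", arm, "/", oar,
             call. = FALSE)
      }
    }
  }
  structure(list(n = as.integer(n),
                 modality_mix = modality_mix / sum(modality_mix),
                 dose_marginals = dose_marginals,
                 dose_correlation = dose_correlation,
                 p_pharynx = p_pharynx,
                 p_baseline_dysphagia = p_baseline_dysphagia,
                 truth = truth,
                 miscalibration = miscalibration,
                 dose_ceiling = dose_ceiling,
                 seed = as.integer(seed)),
            class = "cohort_recipe")
}

#' Moments of a doubly truncated normal
#'
#' Closed-form mean and SD of `N(mean, sd)` truncated to
#' `[lower, upper]`; the reference values the generator's dose marginals
#' must reproduce.
#'
#' @param mean,sd Parent normal parameters.
#' @param lower,upper Truncation bounds.
#' @return Named vector `c(mean, sd)` of the truncated distribution.
#' @export
truncnorm_moments <- function(mean, sd, lower = 0, upper = 80) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / Z
  v <- sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Quantile function of the doubly truncated normal, used for the copula
# margin transform.
qtruncnorm <- function(u, mean, sd, lower, upper) {
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  q <- stats::qnorm(pa + u * (pb - pa), mean, sd)
  pmin(pmax(q, lower), upper)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [cohort_recipe()]: modality from the configured
#' mix; the four doses from a Gaussian copula with exchangeable latent
#' correlation and truncated-normal marginals on `[0, dose_ceiling]`;
#' tumour location and baseline dysphagia as independent Bernoulli
#' indicators; and the outcome as Bernoulli with probability
#' `plogis(S)` under the miscalibrated truth model
#' (`apply_miscalibration(truth, miscalibration)`). Identical recipe and
#' seed reproduce the cohort exactly.
#'
#' @param recipe A [cohort_recipe()].
#' @param seed Overrides `recipe$seed` when given (used by the
#'   replication harness).
#' @return A cohort tibble in the standard schema (`patient_id`, four
#'   dose columns, `tumour_location`, `baseline_dysphagia`, `modality`,
#'   `outcome`).
#' @export
generate_cohort <- function(recipe, seed = NULL) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  n <- recipe$n
  set.seed(if (is.null(seed)) recipe$seed else as.integer(seed))

  modality <- sample(c("photon", "photon_chemo", "proton"), n,
                     replace = TRUE, prob = recipe$modality_mix)

  oars <- names(recipe$dose_marginals[["photon"]])
  k <- length(oars)
  rho <- recipe$dose_correlation
  R <- matrix(rho, k, k); diag(R) <- 1
  L <- chol(R)
  Z <- matrix(stats::rnorm(n * k), nrow = n, ncol = k) %*% L
  U <- stats::pnorm(Z)

  arm <- ifelse(modality == "proton", "proton", "photon")
  doses <- matrix(NA_real_, n, k, dimnames = list(NULL, oars))
  for (a in unique(arm)) {
    idx <- arm == a
    for (j in seq_len(k)) {
      m <- recipe$dose_marginals[[a]][[oars[j]]]
      doses[idx, j] <- qtruncnorm(U[idx, j], m[["mean"]], m[["sd"]],
                                  0, recipe$dose_ceiling)
    }
  }

  tumour_location <- stats::rbinom(n, 1, recipe$p_pharynx)
  baseline_dysphagia <- stats::rbinom(n, 1, recipe$p_baseline_dysphagia)

  cohort <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    !!!as.data.frame(doses),
    tumour_location = tumour_location,
    baseline_dysphagia = baseline_dysphagia,
    modality = modality
  )

  gen_model <- apply_miscalibration(recipe$truth, recipe$miscalibration)
  p <- stats::plogis(linear_predictor(cohort, gen_model,
                                      dose_ceiling = NULL))
  cohort$outcome <- stats::rbinom(n, 1, p)
  validate_cohort(cohort)
  cohort
}

# Counter-based per-replicate seed derivation: independent, reproducible,
# and always below 2^31.
derive_seed <- function(master, i) {
  as.integer((as.double(master) %% 2147483647 + i * 1000003) %% 2147483647)
}

#' Monte-Carlo selection frequencies of the closed testing procedure
#'
#' Repeatedly generates cohorts from the recipe and runs the closed
#' testing procedure of the recipe's truth model (the model under
#' validation) on each, tallying which calibration level is selected.
#' Per-replicate seeds are derived from the master seed by a counter
#' scheme, so individual replicates are reproducible in isolation.
#'
#' @param recipe A [cohort_recipe()].
#' @param reps Number of replicates (>= 1).
#' @param alpha_sig Significance level passed to [ctp_select()].
#' @param seed Master seed (defaults to `recipe$seed`).
#' @return Tibble with one row per level: `level`, `count`, `proportion`,
#'   `mc_se` (binomial Monte-Carlo standard error). Replicates whose fits
#'   failed are excluded from the tally and counted in the `n_failed`
#'   attribute.
#' @export
ctp_selection_frequencies <- function(recipe, reps, alpha_sig = 0.05,
                                      seed = NULL) {
  stopifnot(inherits(recipe, "cohort_recipe"), reps >= 1)
  master <- if (is.null(seed)) recipe$seed else as.integer(seed)
  selections <- character(reps)
  for (i in seq_len(reps)) {
    cohort <- generate_cohort(recipe, seed = derive_seed(master, i))
    res <- tryCatch(ctp_select(cohort, recipe$truth, alpha_sig = alpha_sig),
                    error = function(e) NULL)
    selections[i] <- if (is.null(res)) NA_character_ else res$selected
  }
  ok <- !is.na(selections)
  counts <- table(factor(selections[ok], levels = ctp_levels))
  prop <- as.numeric(counts) / sum(ok)
  out <- tibble::tibble(
    level = ctp_levels,
    count = as.integer(counts),
    proportion = prop,
    mc_se = sqrt(prop * (1 - prop) / sum(ok))
  )
  attr(out, "n_failed") <- sum(!ok)
  attr(out, "reps") <- as.integer(reps)
  out
}
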