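# Reading and writing the cohort CSV and model-spec JSON formats.
#
# Cohort CSV schema (comma-separated, UTF-8, "." decimal, header required):
#   patient_id, dmean_oral_cavity, dmean_pcm_superior, dmean_pcm_medium,
#   dmean_pcm_inferior, tumour_location, baseline_dysphagia, modality, outcome
# Doses in Gy; indicators and outcome strictly 0/1;
# modality in {photon, photon_chemo, proton}.

#' Read a cohort CSV
#'
#' Reads and validates a cohort table. Complete cases are enforced: any
#' missing value is an error naming the row and column — no imputation is
#' ever performed.
#'
#' @param path Path to a cohort CSV (schema above).
#' @param require_outcome Require the binary `outcome` column (default
#'   `TRUE`; set `FALSE` for prediction-only tables).
#' @return A validated tibble.
#' @export
read_cohort <- function(path, require_outcome = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            patient_id = readr::col_character(),
                            modality = readr::col_character(),
                            .default = readr::col_double()
                          ))
  validate_cohort(data, require_outcome = require_outcome)
  tibble::as_tibble(data)
}

#' Write a cohort CSV
#'
#' @param data Cohort tibble (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  validate_cohort(data, require_outcome = "outcome" %in% names(data))
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

model_spec_fields <- c("name", "intercept", "coefficients", "coding")

#' Read / write a logistic model spec (JSON)
#'
#' The model-spec JSON has fields `name`, `intercept`,
#' `coefficients` (predictor -> log-odds value) and optional `coding`.
#' Unknown fields and non-finite values are rejected; write-then-read
#' round-trips the in-memory model exactly.
#'
#' @param path Path to a model-spec JSON file.
#' @return `read_model()` returns an [ntcp_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(spec), model_spec_fields)
  if (length(unknown) > 0L) {
    stop("unknown field(s) in model spec: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(spec$intercept) || is.null(spec$coefficients)) {
    stop("model spec must contain 'intercept' and 'coefficients'", call. = FALSE)
  }
  co <- unlist(spec$coefficients)
  ntcp_model(intercept = spec$intercept,
             coefficients = co,
             name = spec$name %||% "model",
             coding = spec$coding %||% default_coding())
}

#' @rdname read_model
#' @param model An [ntcp_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ntcp_model"))
  spec <- list(name = model$name,
               intercept = model$intercept,
               coefficients = as.list(model$coefficients),
               coding = model$coding)
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write a cohort recipe (JSON)
#'
#' The recipe JSON mirrors [cohort_recipe()]: fields `n`, `modality_mix`,
#' `dose_marginals` (arm -> predictor -> {mean, sd}), `dose_correlation`,
#' `p_pharynx`, `p_baseline_dysphagia`, `truth` (an embedded model spec;
#' omitted means the packaged original model), `miscalibration`
#' (`delta_intercept`, `slope_factor`, `coefficient_overrides`),
#' `dose_ceiling`, `seed`. Missing fields take the recipe defaults.
#'
#' @param path Path to a recipe JSON file.
#' @return `read_recipe()` returns a [cohort_recipe()].
#' @export
read_recipe <- function(path) {
  if (!file.exists(path)) stop("recipe file not found: ", path, call. = FALSE)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- if (is.null(spec$truth)) {
    nipp_dysphagia_model()
  } else {
    ntcp_model(spec$truth$intercept, unlist(spec$truth$coefficients),
               name = spec$truth$name %||% "truth",
               coding = spec$truth$coding %||% default_coding())
  }
  mis <- if (is.null(spec$miscalibration)) {
    miscalibration_spec()
  } else {
    miscalibration_spec(
      delta_intercept = spec$miscalibration$delta_intercept %||% 0,
      slope_factor = spec$miscalibration$slope_factor %||% 1,
      coefficient_overrides = spec$miscalibration$coefficient_overrides
    )
  }
  marg <- if (is.null(spec$dose_marginals)) {
    default_dose_marginals()
  } else {
    lapply(spec$dose_marginals, function(arm) {
      lapply(arm, function(m) c(mean = m$mean %||% m[["mean"]],
                                sd = m$sd %||% m[["sd"]]))
    })
  }
  args <- list(truth = truth, miscalibration = mis, dose_marginals = marg)
  for (f in c("n", "dose_correlation", "p_pharynx", "p_baseline_dysphagia",
              "dose_ceiling", "seed")) {
    if (!is.null(spec[[f]])) args[[f]] <- spec[[f]]
  }
  if (!is.null(spec$modality_mix)) {
    args$modality_mix <- unlist(spec$modality_mix)
  }
  do.call(cohort_recipe, args)
}

#' @rdname read_recipe
#' @param recipe A [cohort_recipe()].
#' @export
write_recipe <- function(recipe, path) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  obj <- list(
    n = recipe$n,
    modality_mix = as.list(recipe$modality_mix),
    dose_marginals = lapply(recipe$dose_marginals, function(arm) {
      lapply(arm, function(m) list(mean = m[["mean"]], sd = m[["sd"]]))
    }),
    dose_correlation = recipe$dose_correlation,
    p_pharynx = recipe$p_pharynx,
    p_baseline_dysphagia = recipe$p_baseline_dysphagia,
    truth = list(name = recipe$truth$name,
                 intercept = recipe$truth$intercept,
                 coefficients = as.list(recipe$truth$coefficients),
                 coding = recipe$truth$coding),
    miscalibration = list(
      delta_intercept = recipe$miscalibration$delta_intercept,
      slope_factor = recipe$miscalibration$slope_factor,
      coefficient_overrides =
        if (is.null(recipe$miscalibration$coefficient_overrides)) NULL
        else as.list(recipe$miscalibration$coefficient_overrides)
    ),
    dose_ceiling = recipe$dose_ceiling,
    seed = recipe$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles the tunable settings of a validation run. The resolved
#' configuration (including the seed) is embedded in every report for
#' provenance.
#'
#' @param alpha_sig Significance level of the closed-testing likelihood
#'   ratio tests (default 0.05).
#' @param hl_groups Number of Hosmer-Lemeshow quantile groups (default 10).
#' @param hl_df_offset Degrees of freedom are `hl_groups - hl_df_offset`;
#'   default offset 2, set 0 for the externally-specified-probability
#'   convention.
#' @param threshold Classification threshold for sensitivity/specificity
#'   (default 0.5), or `"youden"` for the Youden-optimal point.
#' @param span Calibration-curve smoother span (default 0.75).
#' @param ci_method AUC confidence-interval method, `"delong"` or
#'   `"bootstrap"`.
#' @param boot_n Bootstrap resamples when `ci_method = "bootstrap"`.
#' @param dose_ceiling Dose warning ceiling in Gy.
#' @param seed Integer seed controlling every stochastic step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(alpha_sig = 0.05, hl_groups = 10, hl_df_offset = 2,
                       threshold = 0.5, span = 0.75,
                       ci_method = c("delong", "bootstrap"), boot_n = 2000,
                       dose_ceiling = 80, seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(alpha_sig > 0, alpha_sig < 1, hl_groups >= 2,
            span > 0, boot_n >= 1)
  if (!identical(threshold, "youden")) {
    stopifnot(is.numeric(threshold), threshold > 0, threshold < 1)
  }
  structure(list(alpha_sig = alpha_sig, hl_groups = as.integer(hl_groups),
                 hl_df_offset = as.integer(hl_df_offset),
                 threshold = threshold, span = span, ci_method = ci_method,
                 boot_n = as.integer(boot_n), dose_ceiling = dose_ceiling,
                 seed = as.integer(seed)),
            class = "run_config")
}
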