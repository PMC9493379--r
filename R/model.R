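# Logistic NTCP model objects and per-patient prediction.

#' Predictor names of the NIPP grade II-IV dysphagia model
#'
#' The six predictors of the six-month grade II-IV dysphagia NTCP model:
#' mean doses (Gy) to the oral cavity and the superior, middle and inferior
#' pharyngeal constrictor muscles, plus two binary clinical indicators.
#'
#' @return Character vector of predictor column names.
#' @export
dysphagia_predictors <- function() {
  c("dmean_oral_cavity", "dmean_pcm_superior", "dmean_pcm_medium",
    "dmean_pcm_inferior", "tumour_location", "baseline_dysphagia")
}

default_coding <- function() {
  list(
    tumour_location    = list(pharynx = 1, larynx = 0),
    baseline_dysphagia = list(`grade_2_or_higher` = 1, `below_grade_2` = 0)
  )
}

#' Construct a logistic NTCP model
#'
#' A logistic NTCP model is an intercept plus named coefficients on the
#' log-odds scale: the linear predictor for a patient with predictor vector
#' `x` is `S = intercept + sum(coefficients * x)` and the complication
#' probability is `plogis(S)`.
#'
#' @param intercept Intercept on the log-odds scale.
#' @param coefficients Named numeric vector of per-unit log-odds
#'   coefficients; names are predictor column names.
#' @param name Model label used in printing and reports.
#' @param coding Optional list documenting the coding of categorical
#'   predictors (level -> numeric value). Defaults to pharynx = 1 /
#'   larynx = 0 for `tumour_location` and baseline grade >= 2 coded 1 for
#'   `baseline_dysphagia`.
#' @return An object of class `ntcp_model`.
#' @examples
#' m <- ntcp_model(-1, c(dose = 0.05), name = "toy")
#' @export
ntcp_model <- function(intercept, coefficients, name = "ntcp_model",
                       coding = default_coding()) {
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept)) {
    stop("`intercept` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(coefficients) || length(coefficients) < 1L) {
    stop("`coefficients` must be a non-empty named numeric vector", call. = FALSE)
  }
  nm <- names(coefficients)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("`coefficients` must have unique non-empty names", call. = FALSE)
  }
  if (!all(is.finite(coefficients))) {
    stop("all coefficients must be finite; offending: ",
         paste(nm[!is.finite(coefficients)], collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = as.character(name)[1],
         intercept = as.numeric(intercept),
         coefficients = stats::setNames(as.numeric(coefficients), nm),
         coding = coding),
    class = "ntcp_model"
  )
}

#' @export
print.ntcp_model <- function(x, ...) {
  cat("<ntcp_model> ", x$name, "\n", sep = "")
  cat("  intercept: ", format(x$intercept), "\n", sep = "")
  cat("  coefficients:\n")
  for (nm in names(x$coefficients)) {
    cat("    ", format(nm, width = 20), format(x$coefficients[[nm]]), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy an NTCP model into a term/estimate tibble
#'
#' @param x An `ntcp_model`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`; the intercept is
#'   reported as `(Intercept)`.
#' @importFrom generics tidy
#' @method tidy ntcp_model
#' @export
tidy.ntcp_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' The packaged NIPP dysphagia model
#'
#' The original six-month grade II-IV dysphagia NTCP model from the Dutch
#' national indication protocol for proton therapy (NIPP): intercept -4.05,
#' dose coefficients 0.03 (oral cavity), 0.02 (PCM superior), 0.01 (PCM
#' medium), 0.01 (PCM inferior) per Gy, and indicator coefficients 1
#' (pharyngeal tumour location) and 1 (baseline dysphagia grade >= 2).
#' Loaded from the model-spec JSON shipped with the package.
#'
#' @return An `ntcp_model`.
#' @export
nipp_dysphagia_model <- function() {
  read_model(system.file("extdata", "nipp_dysphagia_model.json",
                         package = "ntcpval", mustWork = TRUE))
}

#' @rdname nipp_dysphagia_model
#' @details `nipp_revised_dysphagia_model()` returns the revised
#'   (re-estimated) coefficient set reported alongside the original model;
#'   it is provided for comparison and as a convenient distinct truth model
#'   in simulations.
#' @export
nipp_revised_dysphagia_model <- function() {
  read_model(system.file("extdata", "nipp_dysphagia_model_revised.json",
                         package = "ntcpval", mustWork = TRUE))
}

# Validate the predictor columns of `data` against `model`.
# Returns the numeric predictor matrix (n x k) in model coefficient order.
predictor_matrix <- function(data, model, dose_ceiling = 80) {
  stopifnot(is.data.frame(data))
  need <- names(model$coefficients)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing predictor column(s) required by model '",
         model$name, "': ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(as.data.frame(data)[, need, drop = FALSE])
  if (!is.numeric(X)) stop("predictor columns must be numeric", call. = FALSE)
  if (anyNA(X)) {
    bad <- which(apply(X, 1L, anyNA))
    stop("missing predictor value(s); complete cases are required. Offending record(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  }
  if (any(!is.finite(X))) stop("non-finite predictor value(s)", call. = FALSE)
  dose_cols <- grep("^dmean_", need, value = TRUE)
  if (length(dose_cols) > 0L) {
    D <- X[, dose_cols, drop = FALSE]
    if (any(D < 0)) stop("negative dose value(s) in: ",
                         paste(dose_cols[colSums(D < 0) > 0], collapse = ", "),
                         call. = FALSE)
    if (!is.null(dose_ceiling) && any(D > dose_ceiling)) {
      warning("dose value(s) above the ", dose_ceiling,
              " Gy ceiling in: ",
              paste(dose_cols[colSums(D > dose_ceiling) > 0], collapse = ", "),
              call. = FALSE)
    }
  }
  ind_cols <- intersect(c("tumour_location", "baseline_dysphagia"), need)
  for (ic in ind_cols) {
    if (!all(X[, ic] %in% c(0, 1))) {
      stop("indicator column '", ic, "' must be coded 0/1", call. = FALSE)
    }
  }
  X
}

#' Linear predictor of an NTCP model
#'
#' Computes `S = intercept + sum_i coefficient_i * x_i` for each row of
#' `data`. Every model coefficient must match a column of `data`; a missing
#' column is an error naming the offending predictor.
#'
#' @param data Data frame with one row per patient and one column per
#'   model predictor (extra columns are ignored).
#' @param model An [ntcp_model()].
#' @param dose_ceiling Doses above this value (Gy) trigger a warning
#'   (`NULL` disables the check).
#' @return Numeric vector of log-odds, one per row.
#' @export
linear_predictor <- function(data, model, dose_ceiling = 80) {
  X <- predictor_matrix(data, model, dose_ceiling = dose_ceiling)
  drop(model$intercept + X %*% model$coefficients)
}

#' Predict NTCP for a cohort
#'
#' Appends the linear predictor `.lp` and the complication probability
#' `.ntcp = plogis(.lp)` to the cohort table. Complete cases are required;
#' records with missing predictor values are rejected, not imputed.
#'
#' @inheritParams linear_predictor
#' @return The input as a tibble with columns `.lp` and `.ntcp` added.
#' @examples
#' m <- ntcp_model(0, c(dose = 1))
#' predict_ntcp(data.frame(dose = c(-1, 0, 1)), m)
#' @export
predict_ntcp <- function(data, model, dose_ceiling = 80) {
  if (nrow(data) < 1L) stop("cohort must contain at least one record", call. = FALSE)
  # a model applied to a standard cohort must cover its full predictor set
  cohort_preds <- intersect(dysphagia_predictors(), names(data))
  uncovered <- setdiff(cohort_preds, names(model$coefficients))
  if (length(uncovered) > 0L && length(cohort_preds) == length(dysphagia_predictors())) {
    stop("model '", model$name, "' has no coefficient for cohort predictor(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  lp <- linear_predictor(data, model, dose_ceiling = dose_ceiling)
  out <- tibble::as_tibble(data)
  out$.lp <- lp
  out$.ntcp <- stats::plogis(lp)
  out
}

#' Difference in NTCP between a photon and a proton plan
#'
#' For row-matched photon and proton predictor tables, computes
#' `delta_ntcp = p(photon) - p(proton)` under the same model. A positive
#' value means the proton plan has the lower predicted complication
#' probability, the quantity used in model-based patient selection.
#'
#' @param photon,proton Data frames of predictor columns with equal row
#'   counts; row i of each describes the two candidate plans for patient i.
#' @inheritParams linear_predictor
#' @return Tibble with columns `ntcp_photon`, `ntcp_proton`, `delta_ntcp`.
#' @export
delta_ntcp <- function(photon, proton, model, dose_ceiling = 80) {
  if (nrow(photon) != nrow(proton)) {
    stop("`photon` and `proton` must have the same number of rows", call. = FALSE)
  }
  p_ph <- stats::plogis(linear_predictor(photon, model, dose_ceiling))
  p_pr <- stats::plogis(linear_predictor(proton, model, dose_ceiling))
  tibble::tibble(ntcp_photon = p_ph, ntcp_proton = p_pr,
                 delta_ntcp = p_ph - p_pr)
}

# Clip probabilities away from {0, 1} so Bernoulli log-likelihoods stay finite.
clip_prob <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

#' Bernoulli log-likelihood of predicted probabilities
#'
#' `sum(y * log(p) + (1 - y) * log(1 - p))` with `p` clipped to
#' `[eps, 1 - eps]` so the result is always finite.
#'
#' @param y Binary outcome vector (0/1).
#' @param p Predicted probabilities.
#' @param eps Clipping bound, default `1e-12`.
#' @return A single finite number.
#' @export
log_likelihood <- function(y, p, eps = 1e-12) {
  if (length(y) == 0L) stop("empty prediction set", call. = FALSE)
  if (length(y) != length(p)) stop("`y` and `p` lengths differ", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1", call. = FALSE)
  p <- clip_prob(p, eps)
  sum(y * log(p) + (1 - y) * log1p(-p))
}

# Validate a full cohort table (predictors + modality + outcome).
# Used by read_cohort() and generate_cohort(); returns the tibble invisibly.
validate_cohort <- function(data, predictors = dysphagia_predictors(),
                            require_outcome = TRUE) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 1L) stop("cohort must contain at least one record", call. = FALSE)
  need <- c("patient_id", predictors, "modality",
            if (require_outcome) "outcome")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(need, "patient_id")) {
    v <- data[[col]]
    if (col == "modality") {
      if (anyNA(v)) stop("missing value in column 'modality', row(s): ",
                         paste(utils::head(which(is.na(v)), 10L), collapse = ", "),
                         call. = FALSE)
      bad <- !v %in% c("photon", "photon_chemo", "proton")
      if (any(bad)) stop("invalid modality value(s) in row(s): ",
                         paste(utils::head(which(bad), 10L), collapse = ", "),
                         call. = FALSE)
      next
    }
    if (!is.numeric(v)) stop("column '", col, "' must be numeric", call. = FALSE)
    if (anyNA(v)) {
      stop("missing value in column '", col, "', row(s): ",
           paste(utils::head(which(is.na(v)), 10L), collapse = ", "),
           "; complete cases are required", call. = FALSE)
    }
  }
  if (require_outcome && !all(data$outcome %in% c(0, 1))) {
    bad <- which(!data$outcome %in% c(0, 1))
    stop("'outcome' must be binary 0/1; offending row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  invisible(tibble::as_tibble(data))
}
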