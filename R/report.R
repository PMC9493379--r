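# Full validation report: the closed testing procedure plus the
# discrimination/calibration metric battery for each calibration level.

roc_points <- function(y, p) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]; ys <- y[ord]
  keep <- c(ps[-1] != ps[-length(ps)], TRUE)
  tibble::tibble(
    threshold = ps[keep],
    fpr = (cumsum(ys == 0) / n0)[keep],
    tpr = (cumsum(ys == 1) / n1)[keep]
  ) |> (\(d) dplyr::bind_rows(tibble::tibble(threshold = Inf, fpr = 0, tpr = 0), d))()
}

level_metrics <- function(y, p, level, config) {
  ci <- auc_ci(y, p, method = config$ci_method, boot_n = config$boot_n,
               seed = config$seed)
  ss <- sens_spec(y, p, threshold = config$threshold)
  hl <- hosmer_lemeshow(y, p, g = config$hl_groups,
                        df_offset = config$hl_df_offset)
  curve <- calibration_curve(y, p, span = config$span)
  es <- e_statistics(curve, p)
  list(
    discrimination = tibble::tibble(
      level = level, auc = auc(y, p), auc_low = ci[["low"]],
      auc_high = ci[["high"]], sensitivity = ss[["sensitivity"]],
      specificity = ss[["specificity"]], threshold = ss[["threshold"]]
    ),
    calibration = tibble::tibble(
      level = level, brier = brier_score(y, p),
      hl_statistic = hl$statistic, hl_df = hl$df, hl_p = hl$p_value,
      emax = es[["emax"]], eavg = es[["eavg"]], e90 = es[["e90"]]
    ),
    curve = curve,
    roc = roc_points(y, p)
  )
}

#' Validate a model on a cohort and assemble the full report
#'
#' Runs the closed testing procedure and, for each of the four
#' calibration levels, computes the discrimination summary (AUC with
#' confidence interval, sensitivity, specificity at the configured
#' threshold), the calibration summary (Brier score, Hosmer-Lemeshow
#' test, Emax/Eavg/E90 against the flexible calibration curve) and the
#' calibration and ROC curves. Deterministic given cohort + config.
#'
#' @param data Cohort table with predictors and binary `outcome`.
#' @param model The original [ntcp_model()] under validation.
#' @param config A [run_config()].
#' @return An `ntcp_validation_report`.
#' @export
validation_report <- function(data, model, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  ctp <- ctp_select(data, model, alpha_sig = config$alpha_sig)
  y <- data$outcome
  levels <- lapply(ctp_levels, function(lv) {
    fit <- ctp$fits[[lv]]
    p <- stats::plogis(linear_predictor(data, fit$model,
                                        dose_ceiling = NULL))
    tryCatch(level_metrics(y, p, lv, config),
             error = function(e) {
               stop("metric computation failed for level '", lv, "': ",
                    conditionMessage(e), call. = FALSE)
             })
  })
  names(levels) <- ctp_levels
  structure(list(model_name = model$name, config = config, ctp = ctp,
                 levels = levels, n = nrow(data), n_events = sum(y)),
            class = "ntcp_validation_report")
}

#' @export
print.ntcp_validation_report <- function(x, ...) {
  cat("<ntcp_validation_report> ", x$model_name, "\n", sep = "")
  cat("  n = ", x$n, " (", x$n_events, " events)\n", sep = "")
  cat("  CTP-selected level: ", x$ctp$selected, "\n\n", sep = "")
  print(tidy(x), width = Inf)
  invisible(x)
}

#' Tidy / glance a validation report
#'
#' `tidy()` returns one row per calibration level with the full metric
#' battery; `glance()` the one-row run summary.
#'
#' @param x An `ntcp_validation_report`.
#' @param ... Unused.
#' @method tidy ntcp_validation_report
#' @export
tidy.ntcp_validation_report <- function(x, ...) {
  disc <- dplyr::bind_rows(lapply(x$levels, `[[`, "discrimination"))
  cal <- dplyr::bind_rows(lapply(x$levels, `[[`, "calibration"))
  fits <- dplyr::bind_rows(lapply(x$ctp$fits, glance))
  out <- dplyr::left_join(disc, cal, by = "level")
  out$alpha <- fits$alpha
  out$slope <- fits$slope
  out$log_lik <- fits$log_lik
  out$selected <- out$level == x$ctp$selected
  out
}

#' @rdname tidy.ntcp_validation_report
#' @method glance ntcp_validation_report
#' @export
glance.ntcp_validation_report <- function(x, ...) {
  tibble::tibble(model = x$model_name, n = x$n, n_events = x$n_events,
                 selected = x$ctp$selected,
                 alpha_sig = x$config$alpha_sig,
                 seed = x$config$seed)
}

#' Write a validation report to JSON
#'
#' The JSON embeds the resolved configuration (provenance), the CTP
#' result, the per-level metric battery, and the calibration and ROC
#' curve coordinates, so every figure can be redrawn from the JSON alone.
#'
#' @param report An `ntcp_validation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "ntcp_validation_report"))
  obj <- list(
    package = "ntcpval",
    version = as.character(utils::packageVersion("ntcpval")),
    model = report$model_name,
    n = report$n,
    n_events = report$n_events,
    config = unclass(report$config),
    ctp = ctp_as_list(report$ctp),
    levels = lapply(report$levels, function(lv) {
      list(discrimination = as.list(lv$discrimination[, -1]),
           calibration = as.list(lv$calibration[, -1]),
           calibration_curve = list(p = lv$curve$p, c_hat = lv$curve$c_hat),
           roc = list(fpr = lv$roc$fpr, tpr = lv$roc$tpr))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Plot the calibration curves of all four levels
#'
#' @param object An `ntcp_validation_report`.
#' @param ... Unused.
#' @return A ggplot faceted by calibration level.
#' @method autoplot ntcp_validation_report
#' @export
autoplot.ntcp_validation_report <- function(object, ...) {
  d <- dplyr::bind_rows(lapply(names(object$levels), function(lv) {
    cv <- object$levels[[lv]]$curve
    tibble::tibble(level = lv, p = cv$p, c_hat = cv$c_hat)
  }))
  d$level <- factor(d$level, levels = ctp_levels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p, y = .data$c_hat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_line(colour = "#2166AC", linewidth = 0.7) +
    ggplot2::facet_wrap(~level, nrow = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted probability",
                  y = "Observed proportion (smoothed)",
                  title = "Calibration by update level") +
    ggplot2::theme_minimal()
}

#' Plot the ROC curves of all four levels
#'
#' @param report An `ntcp_validation_report`.
#' @return A ggplot with one ROC curve per calibration level.
#' @export
plot_roc <- function(report) {
  stopifnot(inherits(report, "ntcp_validation_report"))
  d <- dplyr::bind_rows(lapply(names(report$levels), function(lv) {
    rc <- report$levels[[lv]]$roc
    tibble::tibble(level = lv, fpr = rc$fpr, tpr = rc$tpr)
  }))
  d$level <- factor(d$level, levels = ctp_levels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                  colour = .data$level)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = "Level", title = "ROC by update level") +
    ggplot2::theme_minimal()
}
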