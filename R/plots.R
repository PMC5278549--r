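# ggplot2 displays for the fitted objects and report bundles.

#' Forest plot of an estimates table
#'
#' Point estimates with 95% CIs, one row per (outcome, model, method).
#' Odds-ratio rows are drawn on a log x scale is left to the caller; the
#' reference line sits at 1 for odds ratios and 0 for slopes.
#'
#' @param estimates A tibble as produced by `tidy()` on `mr_estimate` objects
#'   (columns `outcome`, `method`, `model_id`, `scale`, `estimate`,
#'   `conf.low`, `conf.high`).
#' @return A ggplot object.
#' @export
plot_forest <- function(estimates) {
  check_data_frame(estimates, "estimates")
  check_columns(estimates, c("outcome", "method", "model_id", "scale",
                             "estimate", "conf.low", "conf.high"),
                arg = "estimates")
  df <- estimates |>
    dplyr::mutate(
      null_value = ifelse(grepl("log-odds", .data$scale), 1, 0),
      label = paste0(.data$method, ", model ", .data$model_id)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label,
                                   colour = .data$method)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$null_value),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$outcome), scales = "free") +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_forest
#' @param object An `mr_report` from [run_longevity_analysis()] or
#'   [run_frailty_analysis()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.mr_report <- function(object, ...) {
  plot_forest(object$estimates) +
    ggplot2::ggtitle(object$design)
}

#' @rdname stage1_fit
#' @param object An `mr_stage1` object.
#' @exportS3Method ggplot2::autoplot
autoplot.mr_stage1 <- function(object, ...) {
  df <- stats::model.frame(object$fit)
  names(df)[1] <- "exposure"
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$g_add), y = .data$exposure)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.25) +
    ggplot2::geom_abline(intercept = object$intercept - object$beta,
                         slope = object$beta, colour = "firebrick") +
    ggplot2::labs(x = "effect-allele count",
                  y = paste0(object$exposure, " (mmol/L)"),
                  title = sprintf("Stage 1: beta = %.3f, F = %.1f, R^2 = %.3f",
                                  object$beta, object$f_stat, object$r2)) +
    ggplot2::theme_minimal()
}

#' @rdname mr_two_stage
#' @param object An `mr_estimate` object.
#' @exportS3Method ggplot2::autoplot
autoplot.mr_estimate <- function(object, ...) {
  if (!is.null(object$replicates)) {
    df <- tibble::tibble(estimate = object$replicates[is.finite(object$replicates)])
    ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate)) +
      ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
      ggplot2::geom_vline(xintercept = object$estimate, colour = "firebrick") +
      ggplot2::labs(x = paste0("bootstrap replicate estimate (", object$scale, ")"),
                    y = "count",
                    title = sprintf("Bootstrap: B = %d, %d failed", object$B,
                                    object$n_failed)) +
      ggplot2::theme_minimal()
  } else {
    plot_forest(tidy(object))
  }
}

#' Frailty-index distribution plot
#'
#' Histogram of the scored frailty index with the frail / non-frail phenotype
#' overlaid when present.
#'
#' @param data A scored cohort (see [score_frailty()]).
#' @return A ggplot object.
#' @export
plot_fi_distribution <- function(data) {
  check_data_frame(data)
  check_columns(data, "fi")
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$fi))
  if ("phenotype" %in% names(data)) {
    p <- p + ggplot2::geom_histogram(ggplot2::aes(fill = .data$phenotype),
                                     bins = 40, position = "stack")
  } else {
    p <- p + ggplot2::geom_histogram(bins = 40, fill = "grey70")
  }
  p + ggplot2::labs(x = "frailty index", y = "subjects") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}
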