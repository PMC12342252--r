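#' Plot tapping signals
#'
#' Amplitude (percent of full stretch) over time for each hand, with detected
#' peaks overlaid when supplied.
#'
#' @param signals Signals tibble (normalized automatically if needed).
#' @param peaks Optional output of [detect_peaks()].
#' @param subjects Optional subset of subject ids to show.
#' @return A ggplot object.
#' @export
plot_signal <- function(signals, peaks = NULL, subjects = NULL) {
  if (!"amplitude_pct" %in% names(signals)) signals <- normalize_signal(signals)
  if (!is.null(subjects)) {
    signals <- dplyr::filter(signals, .data$subject_id %in% subjects)
    if (!is.null(peaks)) {
      peaks <- dplyr::filter(peaks, .data$subject_id %in% subjects)
    }
  }
  p <- ggplot2::ggplot(signals,
                       ggplot2::aes(.data$time_s, .data$amplitude_pct)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(subject_id ~ hand) +
    ggplot2::labs(x = "time (s)", y = "amplitude (% of full stretch)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(peaks, .data$type == "peak"),
      colour = "red", size = 1
    )
  }
  p
}

#' ROC curves per outer fold of a nested-CV fit
#'
#' @param object A `tapkin_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tapkin_cv <- function(object, ...) {
  s <- object$summary
  lab <- sprintf("%s: AUC %.2f ± %.2f", toupper(object$family),
                 s$mean[s$metric == "auc"], s$sd[s$metric == "auc"])
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(.data$fpr, .data$tpr,
                               group = factor(.data$fold),
                               colour = factor(.data$fold))) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = lab, x = "false positive rate",
                  y = "true positive rate", colour = "fold") +
    ggplot2::theme_minimal()
}

#' Bar chart of sampled Shapley feature importances
#'
#' @param importances Output of [rank_features()].
#' @return A ggplot object.
#' @export
plot_importance <- function(importances) {
  ggplot2::ggplot(
    importances,
    ggplot2::aes(.data$importance,
                 stats::reorder(.data$feature, .data$importance))
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |Shapley attribution|", y = NULL) +
    ggplot2::theme_minimal()
}
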