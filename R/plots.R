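#' Plot an aligned signal with detected initial contacts
#'
#' @param object An `accel_aligned` tibble.
#' @param ics Optional `gait_ics` tibble of detected contacts.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accel_aligned <- function(object, ics = NULL, ...) {
  long <- tidyr::pivot_longer(as_tibble(as.data.frame(object)),
                              c("vertical", "ap", "ml"),
                              names_to = "component", values_to = "g")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$g)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "acceleration (g)") +
    ggplot2::theme_minimal()
  if (!is.null(ics) && nrow(ics) > 0) {
    p <- p + ggplot2::geom_vline(
      data = tibble(ic_time = ics$ic_time),
      ggplot2::aes(xintercept = .data$ic_time),
      colour = "firebrick", linetype = "dashed", linewidth = 0.3
    )
  }
  p
}

#' Plot estimated against reference gait parameters
#'
#' One panel per parameter with the identity line; the plot equivalent of
#' the concurrent-validity correlation analysis.
#'
#' @param object A `fog_validation` from [validation_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fog_validation <- function(object, ...) {
  ggplot2::ggplot(object$per_subject,
                  ggplot2::aes(x = .data$reference, y = .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "reference system", y = "accelerometer estimate") +
    ggplot2::theme_minimal()
}

#' Plot per-simulation classifier accuracies
#'
#' @param object A `fog_report_set` from [run_simulations()].
#' @param metric One of `"accuracy"`, `"sensitivity"`, `"specificity"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fog_report_set <- function(object, metric = "accuracy", ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$classifier_kind,
                                     y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = paste0(metric, " (%)")) +
    ggplot2::theme_minimal()
}
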