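#' Plot a fitted temporal kernel
#'
#' @param object A `similarity_kernel` or `kernel_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.similarity_kernel <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$dt_ms, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(-30, 30), linetype = "dotted") +
    ggplot2::labs(x = "t_post - t_pre (ms)", y = "K",
                  title = "Temporal similarity kernel") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.similarity_kernel
#' @export
autoplot.kernel_fit <- function(object, ...) {
  autoplot.similarity_kernel(object$kernel) +
    ggplot2::labs(subtitle = sprintf("held-out r^2 = %.2f", object$r2_test))
}

#' Plot an offset sweep
#'
#' @param object An `offset_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot with the mean detector score (+- SE) per offset and the
#'   argmax marked.
#' @export
autoplot.offset_sweep <- function(object, ...) {
  peak <- object$offset_ms[which.max(object$mean_score)]
  ggplot2::ggplot(object, ggplot2::aes(.data$offset_ms, .data$mean_score)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_score - .data$se,
                                      ymax = .data$mean_score + .data$se),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = peak, linetype = "dashed") +
    ggplot2::labs(x = "pre-before-BAP offset (ms)", y = "mean detector score",
                  title = sprintf("Detector timing preference (argmax %g ms)",
                                  peak)) +
    ggplot2::theme_minimal()
}

#' ROC curve of a detection report
#'
#' @param object A `detection_report`.
#' @param ... Unused.
#' @return A ggplot of TPR vs family-wise FPR with the no-discrimination
#'   diagonal.
#' @export
autoplot.detection_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "family-wise false-positive rate",
                  y = "true-positive rate", title = "ROC") +
    ggplot2::theme_minimal()
}

#' Matched vs random score densities
#'
#' Kernel density estimates of threshold-normalised detector scores for the
#' matched axon and for random axons; 1 is the potentiation threshold.
#'
#' @param matched,null Numeric vectors of normalised scores.
#' @param trans Optional transform applied to both (e.g. `log10` after adding
#'   a floor).
#' @return A ggplot.
#' @export
plot_score_densities <- function(matched, null, trans = identity) {
  df <- dplyr::bind_rows(
    dplyr::mutate(kde_scores(trans(matched)), class = "matched"),
    dplyr::mutate(kde_scores(trans(null)), class = "random"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$density,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = trans(1), linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(matched = "#2166ac",
                                            random = "#b2182b")) +
    ggplot2::labs(x = "normalised calcium integral", y = "density") +
    ggplot2::theme_minimal()
}

#' Raster of a control phase
#'
#' @param object A `control_report`.
#' @param matched_value Optional matched-axon value [spike_train()] to show
#'   beneath the somatic output.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.control_report <- function(object, matched_value = NULL, ...) {
  df <- tibble::tibble(t = object$soma_spikes$times, row = "soma")
  if (!is.null(matched_value)) {
    df <- dplyr::bind_rows(df, tibble::tibble(t = matched_value$times,
                                              row = "matched value"))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$row)) +
    ggplot2::geom_point(shape = "|", size = 5) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%.0f%% successful / %.0f%% spurious",
                                  100 * object$pct_successful,
                                  100 * object$pct_spurious)) +
    ggplot2::theme_minimal()
}
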