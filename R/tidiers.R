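#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted kernel
#'
#' @param x A `kernel_fit`.
#' @param ... Unused.
#' @return A tibble with `dt_ms`, `value` (envelope applied) and `interior`.
#' @export
tidy.kernel_fit <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$kernel),
                interior = attr(x$kernel, "interior"))
}

#' @rdname tidy.kernel_fit
#' @export
glance.kernel_fit <- function(x, ...) {
  tibble::tibble(r2_train = x$r2_train, r2_test = x$r2_test,
                 n_outliers_train = x$n_outliers_train,
                 n_outliers_test = x$n_outliers_test,
                 n_train = x$n_train, n_test = x$n_test,
                 degenerate = x$degenerate)
}

#' @rdname tidy.kernel_fit
#' @export
glance.threshold_calibration <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, target = x$target,
                 n_null_sims = x$n_null_sims, window = x$window)
}

#' Tidy the ROC curve of a detection report
#'
#' @param x A `detection_report`.
#' @param ... Unused.
#' @return The ROC tibble (`fpr`, `tpr`, `threshold`).
#' @export
tidy.detection_report <- function(x, ...) x$roc

#' @rdname tidy.detection_report
#' @export
glance.detection_report <- function(x, ...) {
  tibble::tibble(window = x$window, jitter_sd_ms = x$jitter_sd_ms,
                 tpr = x$tpr, familywise_fpr = x$familywise_fpr,
                 threshold = x$threshold, n_matched = x$n_matched,
                 n_null_runs = x$n_null_runs)
}

#' @rdname tidy.detection_report
#' @export
glance.control_report <- function(x, ...) {
  tibble::tibble(pct_successful = x$pct_successful,
                 pct_spurious = x$pct_spurious,
                 n_value_spikes = x$n_value_spikes,
                 n_soma_spikes = x$n_soma_spikes,
                 query_rate = x$query_rate)
}
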