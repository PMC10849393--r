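#' Run a batch of null (non-matched) match-phase simulations
#'
#' Each run draws a fresh somatic query and `n_null` independent random key
#' trains, scores every spine group, and records the per-run maximum score —
#' the statistic that the family-wise threshold is calibrated on.
#'
#' @param n_runs Number of independent runs.
#' @param window Match window, seconds.
#' @param geometry A [build_geometry()] result.
#' @param params A [spine_params()] list.
#' @param n_null Number of non-matched axons per run (default 149).
#' @param rate,refractory Poisson train parameters.
#' @param dt_ms Time step, ms.
#' @param tail_ms Post-window integration tail, ms.
#' @param seed Integer master seed.
#' @param keep_scores Keep the per-axon score vectors (list-column).
#' @return A tibble with columns `run`, `max_score` and (optionally) `scores`.
#' @export
run_null_batch <- function(n_runs, window = 1, geometry = build_geometry(),
                           params = spine_params(), n_null = 149,
                           rate = 6, refractory = 0.05, dt_ms = 0.1,
                           tail_ms = 100, seed = NULL, keep_scores = FALSE) {
  stopifnot(n_null <= attr(geometry, "n_axons"))
  lat <- geometry$latency_ms[seq_len(n_null)]
  n_steps <- as.integer(ceiling((window * 1000 + max(lat) + tail_ms) / dt_ms))
  p <- unclass(params)
  run_all <- function() {
    res <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      soma_ms <- sample_poisson_refractory(rate, refractory, window)$times * 1000
      pre_list <- lapply(seq_len(n_null), function(i) {
        sample_poisson_refractory(rate, refractory, window)$times * 1000
      })
      bap_list <- lapply(lat, function(l) soma_ms + l)
      res[[r]] <- score_axons_cpp(pre_list, bap_list, n_steps, dt_ms, p, 1)
    }
    res
  }
  res <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())
  out <- tibble::tibble(run = seq_len(n_runs),
                        max_score = vapply(res, max, numeric(1)))
  if (keep_scores) out$scores <- res
  out
}

#' Run a batch of matched match-phase simulations
#'
#' Each run draws a fresh somatic query, assigns the matched axon to a random
#' spine group, builds its presynaptic train 7 ms ahead of the group's BAP
#' arrivals (optionally jittered), and records the matched score. Only the
#' matched spine group is simulated — the null axons do not influence it in
#' the reduced model.
#'
#' @inheritParams run_null_batch
#' @param jitter_sd_ms Gaussian jitter SD applied to the matched train, ms.
#' @param lead Matched lead time, seconds.
#' @return A tibble with columns `run`, `group`, `score`.
#' @export
run_matched_batch <- function(n_runs, window = 1, geometry = build_geometry(),
                              params = spine_params(), jitter_sd_ms = 0,
                              lead = 0.007, rate = 6, refractory = 0.05,
                              dt_ms = 0.1, tail_ms = 100, seed = NULL) {
  n_axons <- attr(geometry, "n_axons")
  p <- unclass(params)
  run_all <- function() {
    grp <- sample.int(n_axons, n_runs, replace = TRUE)
    sc <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      soma <- sample_poisson_refractory(rate, refractory, window)
      arr <- bap_arrivals(soma, geometry, grp[r])
      pre <- make_matched_train(arr, lead)
      if (jitter_sd_ms > 0) pre <- jitter_train(pre, jitter_sd_ms / 1000)
      n_steps <- as.integer(ceiling((arr$duration * 1000 + tail_ms) / dt_ms))
      sc[r] <- spine_score_cpp(pre$times * 1000, arr$times * 1000,
                               n_steps, dt_ms, p)
    }
    tibble::tibble(run = seq_len(n_runs), group = grp, score = sc)
  }
  if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())
}

#' Calibrate the potentiation threshold to a family-wise rejection rate
#'
#' The threshold is the empirical `target`-quantile (linear interpolation
#' between order statistics, quantile type 7) of the per-run maximum score
#' over all null axons, so that in a fraction `target` of null runs no axon
#' crosses it. Normalised scores are raw / threshold, making 1 the threshold
#' for potentiation.
#'
#' @param null_runs A [run_null_batch()] tibble, a numeric vector of per-run
#'   maxima, or a list of per-axon score vectors.
#' @param target Family-wise rejection rate (default 0.9).
#' @param strict Escalate the small-batch warning (< 50 runs) to an error.
#' @param window Window length recorded in the calibration, seconds.
#' @return An object of class `threshold_calibration`.
#' @export
calibrate_threshold <- function(null_runs, target = 0.9, strict = FALSE,
                                window = NA_real_) {
  maxima <-
    if (is.data.frame(null_runs)) null_runs$max_score
    else if (is.list(null_runs)) vapply(null_runs, max, numeric(1))
    else as.numeric(null_runs)
  stopifnot(target > 0, target <= 1, all(is.finite(maxima)))
  if (length(maxima) < 50) {
    msg <- sprintf("threshold calibrated on only %d null runs; the quantile estimate is noisy",
                   length(maxima))
    if (strict) rlang::abort(msg) else rlang::warn(msg)
  }
  structure(
    list(threshold = unname(stats::quantile(maxima, target, type = 7)),
         target = target, n_null_sims = length(maxima), window = window,
         quantile_type = 7),
    class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("<threshold_calibration> threshold %.4g (%.0f%% family-wise rejection, %d null runs)\n",
              x$threshold, 100 * x$target, x$n_null_sims))
  invisible(x)
}

#' @rdname calibrate_threshold
#' @param scores Raw detector scores.
#' @param calibration A `threshold_calibration`.
#' @export
normalize_scores <- function(scores, calibration) {
  stopifnot(inherits(calibration, "threshold_calibration"))
  scores / calibration$threshold
}

#' Evaluate detection performance against a calibrated threshold
#'
#' Computes the true-positive rate (matched scores above threshold), the
#' family-wise false-positive rate (null runs whose maximum crosses it), and
#' the full ROC curve obtained by sweeping the threshold. Matched and null
#' data must come from runs independent of the calibration batch.
#'
#' @param matched_scores Numeric vector of matched-axon scores.
#' @param null_run_maxima Numeric vector of per-run maxima over null axons.
#' @param threshold A number or a [calibrate_threshold()] object.
#' @param window,jitter_sd_ms Condition metadata recorded in the report.
#' @return An object of class `detection_report` with elements `tpr`,
#'   `familywise_fpr`, `roc` (tibble `fpr`, `tpr`, `threshold`), and the
#'   metadata.
#' @export
evaluate_detection <- function(matched_scores, null_run_maxima, threshold,
                               window = NA_real_, jitter_sd_ms = NA_real_) {
  thr <- if (inherits(threshold, "threshold_calibration")) threshold$threshold
         else as.numeric(threshold)
  cuts <- sort(unique(c(matched_scores, null_run_maxima)), decreasing = TRUE)
  roc <- tibble::tibble(
    threshold = c(Inf, cuts),
    tpr = vapply(c(Inf, cuts), function(ct) mean(matched_scores >= ct), numeric(1)),
    fpr = vapply(c(Inf, cuts), function(ct) mean(null_run_maxima >= ct), numeric(1)))
  structure(
    list(tpr = mean(matched_scores > thr),
         familywise_fpr = mean(null_run_maxima > thr),
         threshold = thr,
         roc = roc[, c("fpr", "tpr", "threshold")],
         n_matched = length(matched_scores),
         n_null_runs = length(null_run_maxima),
         window = window, jitter_sd_ms = jitter_sd_ms),
    class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> TPR %.1f%%, family-wise FPR %.1f%% (window %s s, jitter %s ms)\n",
              100 * x$tpr, 100 * x$familywise_fpr,
              format(x$window), format(x$jitter_sd_ms)))
  invisible(x)
}

#' Kernel density estimate of a score distribution
#'
#' Thin wrapper over [stats::density()] returning a tibble, used for the
#' matched-vs-random score distribution figures.
#'
#' @param scores Numeric vector (>= 10 values).
#' @param bw Bandwidth rule or number (see [stats::density()]).
#' @param n Grid size.
#' @param from,to Optional grid limits.
#' @return A tibble with columns `x` and `density`; attribute `bw`.
#' @export
kde_scores <- function(scores, bw = "nrd0", n = 512, from = NULL, to = NULL) {
  stopifnot(length(scores) >= 10)
  args <- list(x = scores, bw = bw, n = n)
  if (!is.null(from)) args$from <- from
  if (!is.null(to)) args$to <- to
  d <- do.call(stats::density, args)
  structure(tibble::tibble(x = d$x, density = d$y), bw = d$bw)
}
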