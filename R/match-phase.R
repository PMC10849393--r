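#' Tabulated temporal similarity kernel
#'
#' The bilinear surrogate of the calcium detector: the detector score of a
#' (pre, post) train pair is modelled as `sum_{t_pre} sum_{t_post}
#' K(t_post - t_pre)`. `K` is tabulated on a millisecond grid and multiplied
#' by a fixed double-sigmoid envelope that forces exponential decay (10 ms
#' time constant) outside the `[-30, 30]` ms window.
#'
#' @param grid_ms Grid of time differences in ms (default -50..50 at 1 ms).
#' @param interior Kernel interior values on the grid (before the envelope).
#' @param window_ms Half-width of the flat envelope region, ms.
#' @param env_tau_ms Envelope decay time constant, ms.
#' @return A tibble of class `similarity_kernel` with columns `dt_ms` and
#'   `value` (envelope applied); the raw interior is kept as an attribute.
#' @export
make_kernel <- function(grid_ms = seq(-50, 50, by = 1), interior = 0,
                        window_ms = 30, env_tau_ms = 10) {
  stopifnot(!is.unsorted(grid_ms), min(grid_ms) <= -window_ms,
            max(grid_ms) >= window_ms)
  interior <- rep_len(interior, length(grid_ms))
  stopifnot(all(is.finite(interior)))
  env <- kernel_envelope(grid_ms, window_ms, env_tau_ms)
  out <- tibble::tibble(dt_ms = as.numeric(grid_ms), value = env * interior)
  structure(out, class = c("similarity_kernel", class(out)),
            interior = interior, window_ms = window_ms, env_tau_ms = env_tau_ms)
}

#' @rdname make_kernel
#' @param t_ms Time differences, ms.
#' @export
kernel_envelope <- function(t_ms, window_ms = 30, env_tau_ms = 10) {
  stats::plogis((t_ms + window_ms) / env_tau_ms) *
    stats::plogis((window_ms - t_ms) / env_tau_ms)
}

#' Evaluate a kernel by linear interpolation
#'
#' @param kernel A [make_kernel()] object.
#' @param t_ms Time differences, ms; values outside the grid evaluate to 0
#'   (the envelope has already decayed there).
#' @return Numeric vector of kernel heights.
#' @export
eval_kernel <- function(kernel, t_ms) {
  out <- numeric(length(t_ms))
  inside <- t_ms >= kernel$dt_ms[1] & t_ms <= kernel$dt_ms[nrow(kernel)]
  if (any(inside)) {
    out[inside] <- stats::approx(kernel$dt_ms, kernel$value,
                                 xout = t_ms[inside])$y
  }
  out
}

#' Predicted detector score under the bilinear kernel model
#'
#' Sums the kernel over all (pre, post) spike-time differences. With a
#' delta-like kernel this reduces to the Euclidean inner product of the two
#' binned spike trains; the fitted kernel makes it a temporally smeared dot
#' product.
#'
#' @param kernel A [make_kernel()] object.
#' @param pre Presynaptic [spike_train()].
#' @param post_arrivals Spine-local BAP arrival [spike_train()].
#' @return The predicted score (kernel units).
#' @export
predict_kernel_model <- function(kernel, pre, post_arrivals) {
  stopifnot(inherits(pre, "spike_train"), inherits(post_arrivals, "spike_train"))
  if (n_spikes(pre) == 0 || n_spikes(post_arrivals) == 0) return(0)
  d <- outer(post_arrivals$times, pre$times, "-") * 1000
  sum(eval_kernel(kernel, as.vector(d)))
}

#' Score every axon of an ensemble against the somatic query
#'
#' Runs the reduced spine model once per spine group (each axon's presynaptic
#' train against its group's BAP arrival train) and returns the raw detector
#' scores.
#'
#' @param ensemble A [gen_ensemble()] tibble.
#' @param soma Somatic [spike_train()].
#' @param geometry A [build_geometry()] result.
#' @param params A [spine_params()] list.
#' @param dt_ms Simulation time step, ms.
#' @param tail_ms Extra integration time after the window so late calcium
#'   transients are counted, ms.
#' @param seed Optional integer seed (noise).
#' @param epsp_mult Scalar or per-axon EPSP multiplier (potentiation factors).
#' @return The ensemble tibble with a `score` column appended.
#' @export
score_ensemble <- function(ensemble, soma, geometry, params = spine_params(),
                           dt_ms = 0.1, tail_ms = 100, seed = NULL,
                           epsp_mult = 1) {
  stopifnot(inherits(ensemble, "train_ensemble"))
  window <- attr(ensemble, "window")
  if (abs(window - soma$duration) > 1e-12) {
    rlang::abort("ensemble window and soma duration differ")
  }
  lat <- geometry$latency_ms[seq_len(nrow(ensemble))]
  soma_ms <- soma$times * 1000
  pre_list <- purrr::map(ensemble$train, function(tr) tr$times * 1000)
  bap_list <- purrr::map(lat, function(l) soma_ms + l)
  n_steps <- as.integer(ceiling((window * 1000 + max(lat) + tail_ms) / dt_ms))
  run <- function() score_axons_cpp(pre_list, bap_list, n_steps, dt_ms,
                                    unclass(params), as.numeric(epsp_mult))
  sc <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  dplyr::mutate(tibble::as_tibble(ensemble), score = sc)
}

#' Remove high outliers from a score list
#'
#' Drops scores more than `k_sd` standard deviations above the mean, with
#' mean and SD computed once on the full list (no iteration). A zero-SD list
#' is kept whole.
#'
#' @param scores Numeric vector (length >= 2).
#' @param k_sd Cut in SD units (default 4).
#' @return A list with `kept` (the surviving scores), `n_removed`, and the
#'   logical `keep` mask.
#' @export
remove_outliers <- function(scores, k_sd = 4) {
  stopifnot(length(scores) >= 2)
  s <- stats::sd(scores)
  keep <- if (!is.finite(s) || s == 0 || !is.finite(k_sd)) {
    rep(TRUE, length(scores))
  } else {
    scores <= mean(scores) + k_sd * s
  }
  list(kept = scores[keep], n_removed = sum(!keep), keep = keep)
}

#' Generate the kernel-fit dataset
#'
#' Runs `n_sims` independent match-phase simulations (one somatic query, 150
#' axonal keys each by default) and collects every (pre train, BAP arrival
#' train, detector score) triple.
#'
#' @inheritParams score_ensemble
#' @param n_sims Number of simulations.
#' @param window Match window, seconds.
#' @param n_matched Matched axons per simulation.
#' @param rate,refractory Poisson train parameters.
#' @param seed Integer master seed.
#' @return A tibble with columns `sim`, `axon`, `matched`, list-columns
#'   `pre` and `post`, and `score`.
#' @export
score_dataset <- function(n_sims = 100, window = 1, geometry = build_geometry(),
                          params = spine_params(), n_matched = 1,
                          rate = 6, refractory = 0.05, dt_ms = 0.1,
                          seed = NULL) {
  run_all <- function() {
    purrr::map_dfr(seq_len(n_sims), function(s) {
      soma <- sample_poisson_refractory(rate, refractory, window)
      ens <- gen_ensemble(soma, geometry, n_matched = n_matched,
                          rate = rate, refractory = refractory)
      scored <- score_ensemble(ens, soma, geometry, params, dt_ms = dt_ms)
      post <- purrr::map(scored$axon, function(g) bap_arrivals(soma, geometry, g))
      tibble::tibble(sim = s, axon = scored$axon, matched = scored$matched,
                     pre = scored$train, post = post, score = scored$score)
    })
  }
  if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())
}

#' Fit the temporal kernel by least squares
#'
#' The model is linear in the tabulated kernel interior (each spike-time
#' difference contributes its two linear-interpolation weights times the
#' fixed envelope), so the least-squares problem is solved exactly with a
#' linear solver. Simulations are split into train/test sets; high outliers
#' (default 4 SD above the pooled mean) are removed before fitting, and the
#' fit is judged by variance explained on the held-out split.
#'
#' @param dataset A [score_dataset()] tibble (columns `sim`, `pre`, `post`,
#'   `score`).
#' @param grid_ms Kernel grid, ms.
#' @param train_frac Fraction of simulations in the training split.
#' @param k_sd Outlier cut in SD units.
#' @param window_ms,env_tau_ms Envelope parameters (see [make_kernel()]).
#' @param seed Integer seed for the split.
#' @return An object of class `kernel_fit`: the fitted kernel plus a fit
#'   report (`r2_train`, `r2_test`, outlier counts, split sizes).
#' @export
fit_kernel <- function(dataset, grid_ms = seq(-50, 50, by = 1),
                       train_frac = 0.85, k_sd = 4,
                       window_ms = 30, env_tau_ms = 10, seed = NULL) {
  stopifnot(nrow(dataset) > 0)
  sims <- unique(dataset$sim)
  pick <- function() sample(sims, max(1, round(train_frac * length(sims))))
  train_sims <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  is_train <- dataset$sim %in% train_sims

  if (all(dataset$score == 0)) {
    k <- make_kernel(grid_ms, 0, window_ms, env_tau_ms)
    return(new_kernel_fit(k, NA_real_, NA_real_, 0L, 0L,
                          sum(is_train), sum(!is_train), degenerate = TRUE))
  }

  keep <- remove_outliers(dataset$score, k_sd)$keep
  X <- kernel_design(dataset$pre, dataset$post, grid_ms, window_ms, env_tau_ms)
  y <- dataset$score

  tr <- keep & is_train
  te <- keep & !is_train
  fit <- stats::lm.fit(X[tr, , drop = FALSE], y[tr])
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  kernel <- make_kernel(grid_ms, beta, window_ms, env_tau_ms)

  r2 <- function(idx) {
    if (!any(idx)) return(NA_real_)
    pred <- as.vector(X[idx, , drop = FALSE] %*% beta)
    1 - sum((y[idx] - pred)^2) / sum((y[idx] - mean(y[idx]))^2)
  }
  new_kernel_fit(kernel, r2(tr), r2(te),
                 n_outliers_train = sum(!keep & is_train),
                 n_outliers_test = sum(!keep & !is_train),
                 n_train = sum(is_train), n_test = sum(!is_train))
}

new_kernel_fit <- function(kernel, r2_train, r2_test, n_outliers_train,
                           n_outliers_test, n_train, n_test,
                           degenerate = FALSE) {
  structure(
    list(kernel = kernel, r2_train = r2_train, r2_test = r2_test,
         n_outliers_train = n_outliers_train, n_outliers_test = n_outliers_test,
         n_train = n_train, n_test = n_test, degenerate = degenerate),
    class = "kernel_fit")
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat("<kernel_fit>",
      if (x$degenerate) "degenerate (all-zero scores); zero kernel\n" else
        sprintf("r2 train %.3f / test %.3f; outliers %d+%d of %d+%d\n",
                x$r2_train, x$r2_test, x$n_outliers_train, x$n_outliers_test,
                x$n_train, x$n_test))
  invisible(x)
}

# design matrix: row per (pre, post) pair set, column per grid node; entry =
# envelope times interpolation weight summed over pairs
kernel_design <- function(pre_list, post_list, grid_ms, window_ms, env_tau_ms) {
  g1 <- grid_ms[1]
  step <- grid_ms[2] - grid_ms[1]
  ng <- length(grid_ms)
  n <- length(pre_list)
  X <- matrix(0, n, ng)
  for (i in seq_len(n)) {
    pre <- pre_list[[i]]$times
    post <- post_list[[i]]$times
    if (length(pre) == 0 || length(post) == 0) next
    d <- as.vector(outer(post, pre, "-")) * 1000
    d <- d[d >= grid_ms[1] & d <= grid_ms[ng]]
    if (length(d) == 0) next
    env <- kernel_envelope(d, window_ms, env_tau_ms)
    pos <- (d - g1) / step
    j <- pmin(floor(pos), ng - 2)
    w <- pos - j
    row <- numeric(ng)
    lo <- tabulate_weighted(j + 1, env * (1 - w), ng)
    hi <- tabulate_weighted(j + 2, env * w, ng)
    X[i, ] <- lo + hi
  }
  X
}

tabulate_weighted <- function(bins, w, nbins) {
  as.vector(tapply(w, factor(bins, levels = seq_len(nbins)), sum,
                   default = 0))
}

#' Sweep the pre-before-BAP offset
#'
#' Measures the mean detector score as a function of the lead time of
#' presynaptic spikes relative to spine BAP arrivals (positive offset = pre
#' before BAP). The curve's argmax is the detector's preferred timing.
#'
#' @param offsets_ms Offsets to test, ms.
#' @param reps Simulations per offset.
#' @param window Window length, seconds.
#' @param params A [spine_params()] list.
#' @param rate,refractory Somatic Poisson parameters.
#' @param dt_ms Time step, ms.
#' @param seed Integer master seed.
#' @return A tibble of class `offset_sweep`: `offset_ms`, `mean_score`, `se`,
#'   `n`.
#' @export
offset_sweep <- function(offsets_ms = -20:30, reps = 300, window = 1,
                         params = spine_params(), rate = 6, refractory = 0.05,
                         dt_ms = 0.1, seed = NULL) {
  n_steps <- as.integer(ceiling((window * 1000 + 100) / dt_ms))
  p <- unclass(params)
  run_all <- function() {
    acc <- matrix(0, reps, length(offsets_ms))
    for (r in seq_len(reps)) {
      soma <- sample_poisson_refractory(rate, refractory, window)
      bap_ms <- soma$times * 1000
      for (k in seq_along(offsets_ms)) {
        pre_ms <- bap_ms - offsets_ms[k]
        pre_ms <- pre_ms[pre_ms >= 0 & pre_ms < window * 1000]
        acc[r, k] <- spine_score_cpp(pre_ms, bap_ms, n_steps, dt_ms, p)
      }
    }
    acc
  }
  acc <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())
  out <- tibble::tibble(
    offset_ms = as.numeric(offsets_ms),
    mean_score = colMeans(acc),
    se = apply(acc, 2, stats::sd) / sqrt(reps),
    n = reps)
  structure(out, class = c("offset_sweep", class(out)))
}
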