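#' Smoothed overlap between a query and a key
#'
#' The exact similarity score of the sparse-attention reference semantics:
#' the kernel summed over all (key spike, query spike) time differences.
#' Shares its implementation with [predict_kernel_model()] — the oracle and
#' the bilinear surrogate are the same bilinear form by contract.
#'
#' @param query Query [spike_train()] (plays the postsynaptic role).
#' @param key Key [spike_train()] (presynaptic role).
#' @param kernel A [make_kernel()] object.
#' @return The overlap score.
#' @export
smoothed_overlap <- function(query, key, kernel) {
  predict_kernel_model(kernel, pre = key, post_arrivals = query)
}

#' Exact hard sparse attention over spike trains
#'
#' Reference implementation of the computation the neuron emulates: score
#' every key against the query with the smoothed overlap, select all keys
#' above the threshold (hard selection, not softmax), and output the union
#' of the selected value trains. An empty selection yields an empty output —
#' the no-match failure case.
#'
#' @param query Query [spike_train()].
#' @param keys List of key [spike_train()]s.
#' @param values List of value [spike_train()]s, aligned one-to-one with
#'   `keys`.
#' @param kernel A [make_kernel()] object.
#' @param threshold Selection threshold (> 0), in kernel score units.
#' @return A list of class `attention_result`: `selected` (indices),
#'   `scores`, and `output` (a [spike_train()]).
#' @export
attend <- function(query, keys, values, kernel, threshold) {
  stopifnot(length(keys) == length(values), threshold > 0)
  scores <- vapply(keys, function(k) smoothed_overlap(query, k, kernel),
                   numeric(1))
  sel <- which(scores > threshold)
  window <- if (length(values) > 0) max(vapply(values, function(v) v$duration,
                                               numeric(1))) else 1
  output <- if (length(sel) > 0) merge_trains(values[sel], window)
            else spike_train(numeric(0), window)
  structure(list(selected = sel, scores = scores, output = output),
            class = "attention_result")
}

#' @export
print.attention_result <- function(x, ...) {
  cat(sprintf("<attention_result> %d/%d keys selected; output has %d spikes\n",
              length(x$selected), length(x$scores), n_spikes(x$output)))
  invisible(x)
}

#' Oracle-simulator selection agreement
#'
#' Runs noiseless match-phase simulations and compares the set of spine
#' groups the simulator would potentiate (raw score above the calibrated
#' threshold) with the keys the exact hard-attention oracle selects using
#' the fitted kernel and the same threshold. On noiseless runs the two
#' selections should agree on nearly all instances.
#'
#' @param n_instances Number of random instances.
#' @param window Match window, seconds.
#' @param geometry A [build_geometry()] result (a reduced axon count keeps
#'   this check fast).
#' @param params A [spine_params()] list; noise is forced off.
#' @param kernel Optional fitted [make_kernel()]; fitted from a noiseless
#'   dataset of `fit_sims` simulations when `NULL`.
#' @param threshold Optional raw threshold; calibrated at the 90% family-wise
#'   level from `calib_runs` noiseless null runs when `NULL`.
#' @param fit_sims,calib_runs Sizes of the internal fit/calibration stages.
#' @param rate,refractory Poisson parameters.
#' @param dt_ms Time step, ms.
#' @param seed Integer master seed.
#' @param kernel_csv Optional path to a saved kernel CSV (columns `dt_ms`,
#'   `interior`), overriding `kernel`.
#' @return A list: `agreement` (fraction of instances with identical
#'   selected sets), `instances` (per-instance tibble), `kernel`,
#'   `threshold`.
#' @export
oracle_agreement <- function(n_instances = 50, window = 1,
                             geometry = build_geometry(30, 10, 6),
                             params = spine_params(), kernel = NULL,
                             threshold = NULL, fit_sims = 25,
                             calib_runs = 80, rate = 6, refractory = 0.05,
                             dt_ms = 0.1, seed = NULL, kernel_csv = NULL) {
  params$noise_sd <- 0
  if (!is.null(kernel_csv)) {
    kdf <- utils::read.csv(kernel_csv)
    kernel <- make_kernel(kdf$dt_ms, kdf$interior)
  }
  run_all <- function() {
    if (is.null(kernel)) {
      ds <- score_dataset(fit_sims, window, geometry, params,
                          rate = rate, refractory = refractory, dt_ms = dt_ms)
      kernel <<- fit_kernel(ds)$kernel
    }
    if (is.null(threshold)) {
      nb <- run_null_batch(calib_runs, window, geometry, params,
                           n_null = attr(geometry, "n_axons"),
                           rate = rate, refractory = refractory, dt_ms = dt_ms)
      threshold <<- calibrate_threshold(nb, window = window)$threshold
    }
    purrr::map_dfr(seq_len(n_instances), function(i) {
      soma <- sample_poisson_refractory(rate, refractory, window)
      ens <- gen_ensemble(soma, geometry, n_matched = 1,
                          rate = rate, refractory = refractory)
      scored <- score_ensemble(ens, soma, geometry, params, dt_ms = dt_ms)
      sim_sel <- which(scored$score > threshold)
      keys <- scored$train
      posts <- purrr::map(scored$axon, function(g) bap_arrivals(soma, geometry, g))
      pred <- purrr::map2_dbl(keys, posts, function(k, po) {
        predict_kernel_model(kernel, k, po)
      })
      ora_sel <- which(pred > threshold)
      tibble::tibble(instance = i,
                     n_sim = length(sim_sel), n_oracle = length(ora_sel),
                     agree = identical(sim_sel, ora_sel))
    })
  }
  inst <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())
  list(agreement = mean(inst$agree), instances = inst,
       kernel = kernel, threshold = threshold)
}
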