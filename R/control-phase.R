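#' Potentiation sigmoid
#'
#' Maps the threshold-normalised detector score to the target potentiation
#' factor of the fast (AMPA) synaptic conductance: ~1 well below threshold,
#' ~8 at and above it. The centre sits just below 1 so that a score exactly
#' at threshold is already nearly fully potentiated.
#'
#' @param normalized_score Score in threshold units (1 = potentiation
#'   threshold); vectorised.
#' @param floor,ceiling Factor range (default 1 to 8).
#' @param center,width Sigmoid centre and width in normalised-score units.
#' @return Target potentiation factor(s).
#' @examples
#' potentiation_sigmoid(c(0, 0.92, 2)) # ~1, 4.5, ~8
#' @export
potentiation_sigmoid <- function(normalized_score, floor = 1, ceiling = 8,
                                 center = 0.92, width = 0.03) {
  stopifnot(all(normalized_score >= 0))
  floor + (ceiling - floor) * stats::plogis((normalized_score - center) / width)
}

#' First-order lag on the potentiation factor
#'
#' EPSP sizes cannot change instantaneously, so the factor relaxes toward its
#' sigmoid target through a first-order low-pass with time constant
#' `lag_tau` (default 0.5 s). The recursion is the exact exponential update,
#' so a constant target gives `f(t) = target + (f0 - target) * exp(-t/tau)`.
#'
#' @param target Target-factor trajectory (numeric vector, one value per
#'   step).
#' @param lag_tau Lag time constant, seconds.
#' @param dt Time step, seconds (must be well below `lag_tau`).
#' @param init Initial factor (default 1, the unpotentiated baseline).
#' @return Factor trajectory, same length as `target`.
#' @export
apply_lag <- function(target, lag_tau = 0.5, dt, init = 1) {
  stopifnot(lag_tau > 0, dt > 0, dt <= lag_tau / 10)
  a <- exp(-dt / lag_tau)
  f <- numeric(length(target))
  cur <- init
  for (i in seq_along(target)) {
    cur <- target[i] + (cur - target[i]) * a
    f[i] <- cur
  }
  f
}

# closed-form lag endpoint for a constant target
lag_endpoint <- function(init, target, elapsed, lag_tau = 0.5) {
  target + (init - target) * exp(-elapsed / lag_tau)
}

#' Control-phase transmission parameters
#'
#' Reduced all-or-none dendritic-spike relay: an axon whose potentiation
#' factor reaches `relay_factor` initiates a dendritic spike for each of its
#' value spikes, which reaches the soma after `latency` with probability
#' `p_success`; the soma enforces a refractory period and also fires
#' background (spurious) spikes at a small Poisson rate driven by membrane
#' noise.
#'
#' @param relay_factor Minimum factor for relay (default 6, near-saturated
#'   potentiation).
#' @param latency Dendrite-to-soma transmission latency, seconds.
#' @param p_success Per-spike transmission probability.
#' @param refractory Somatic refractory period, seconds.
#' @param spurious_rate Background somatic spike rate, Hz.
#' @return A list of class `control_params`.
#' @export
control_params <- function(relay_factor = 6, latency = 0.003,
                           p_success = 0.95, refractory = 0.005,
                           spurious_rate = 0.3) {
  p <- as.list(environment())
  stopifnot(p$relay_factor > 1, p$latency >= 0, p$p_success >= 0,
            p$p_success <= 1, p$refractory >= 0, p$spurious_rate >= 0)
  structure(p, class = "control_params")
}

#' Simulate the control phase
#'
#' Axons whose potentiation factor reaches the relay threshold drive the soma
#' with their value trains; everything else contributes only background noise
#' spikes. Somatic spikes are then classified against the matched axon's
#' value train as successful or spurious.
#'
#' @param value_trains List of [spike_train()]s, one per axon, on the control
#'   window.
#' @param factors Numeric potentiation factor per axon at control onset.
#' @param matched_index Indices of the matched axon(s); their value spikes
#'   define "successful" somatic spikes.
#' @param ctrl A [control_params()] list.
#' @param seed Optional integer seed.
#' @param query_rate Query spike rate during the match phase, Hz (metadata).
#' @param continue_potentiation If `TRUE`, every already-potentiated axon
#'   keeps integrating calcium during the control phase (its own potentiated
#'   EPSPs open NMDA receptors without BAPs) and its factor keeps relaxing
#'   toward the updated sigmoid target; requires `threshold` and
#'   `spine_par`.
#' @param norm_scores Normalised match-phase scores (needed with
#'   `continue_potentiation`).
#' @param threshold Raw potentiation threshold (needed with
#'   `continue_potentiation`).
#' @param spine_par A [spine_params()] list (needed with
#'   `continue_potentiation`).
#' @param lag_tau Potentiation lag, seconds.
#' @return An object of class `control_report`: the somatic train, the
#'   successful/spurious percentages, counts, and end-of-phase factors.
#' @export
simulate_control <- function(value_trains, factors, matched_index = integer(0),
                             ctrl = control_params(), seed = NULL,
                             query_rate = NA_real_,
                             continue_potentiation = FALSE,
                             norm_scores = NULL, threshold = NULL,
                             spine_par = NULL, lag_tau = 0.5) {
  stopifnot(length(value_trains) == length(factors))
  window <- value_trains[[1]]$duration
  run <- function() {
    relays <- which(factors >= ctrl$relay_factor)
    relay_times <- numeric(0)
    for (i in relays) {
      t <- value_trains[[i]]$times + ctrl$latency
      t <- t[stats::runif(length(t)) < ctrl$p_success]
      relay_times <- c(relay_times, t)
    }
    spur <- if (ctrl$spurious_rate > 0)
      sample_poisson_refractory(ctrl$spurious_rate, 0, window)$times
    else numeric(0)
    all_t <- sort(c(relay_times, spur))
    all_t <- all_t[all_t < window]
    kept <- numeric(0)
    last <- -Inf
    for (t in all_t) {
      if (t - last >= ctrl$refractory) {
        kept <- c(kept, t)
        last <- t
      }
    }
    kept
  }
  soma_t <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  soma <- spike_train(soma_t, window, label = "control soma")

  matched_value <- if (length(matched_index) > 0) {
    merge_trains(value_trains[matched_index], window)
  } else spike_train(numeric(0), window)
  cls <- classify_spikes(soma, matched_value)

  factors_end <- factors
  if (continue_potentiation) {
    stopifnot(!is.null(norm_scores), !is.null(threshold), !is.null(spine_par))
    pot <- which(factors > 1.05)
    for (i in pot) {
      tr <- simulate_spine(value_trains[[i]],
                           spike_train(numeric(0), window),
                           spine_par, epsp_mult = factors[i])
      extra <- attr(tr, "score")
      new_norm <- norm_scores[i] + extra / threshold
      tgt <- potentiation_sigmoid(new_norm)
      factors_end[i] <- lag_endpoint(factors[i], tgt, window, lag_tau)
    }
  }

  structure(
    list(soma_spikes = soma,
         pct_successful = cls$pct_successful,
         pct_spurious = cls$pct_spurious,
         n_successful = cls$n_successful,
         n_value_spikes = cls$n_value,
         n_spurious = cls$n_spurious,
         n_soma_spikes = cls$n_soma,
         undefined_successful = cls$undefined_successful,
         undefined_spurious = cls$undefined_spurious,
         query_rate = query_rate,
         factors_end = factors_end),
    class = "control_report")
}

merge_trains <- function(trains, window) {
  t <- sort(unlist(lapply(trains, function(x) x$times)))
  if (length(t) > 1) t <- t[c(TRUE, diff(t) > 0)]
  spike_train(t, window)
}

#' @export
print.control_report <- function(x, ...) {
  cat(sprintf("<control_report> %d somatic spikes; %.0f%% successful, %.0f%% spurious\n",
              x$n_soma_spikes, 100 * x$pct_successful, 100 * x$pct_spurious))
  invisible(x)
}

#' Classify somatic spikes as successful or spurious
#'
#' A matched-axon value spike is successful when a somatic spike follows it
#' within `window` seconds (greedy earliest-first one-to-one matching). A
#' somatic spike is spurious when no matched-axon value spike precedes it
#' within the same window. Empty denominators yield 0 with an `undefined_*`
#' flag.
#'
#' @param soma Somatic [spike_train()] of the control phase.
#' @param matched_value Matched-axon value [spike_train()].
#' @param window Attribution window, seconds (default 0.020).
#' @return A list: `pct_successful`, `pct_spurious`, counts, and
#'   `undefined_*` flags for 0/0 fractions.
#' @export
classify_spikes <- function(soma, matched_value, window = 0.020) {
  v <- matched_value$times
  s <- soma$times
  used <- rep(FALSE, length(s))
  n_succ <- 0L
  j <- 1L
  for (t in v) {
    while (j <= length(s) && s[j] <= t) j <- j + 1L
    k <- j
    while (k <= length(s) && s[k] <= t + window) {
      if (!used[k]) {
        used[k] <- TRUE
        n_succ <- n_succ + 1L
        break
      }
      k <- k + 1L
    }
  }
  preceded <- vapply(s, function(t) any(v >= t - window & v < t), logical(1))
  n_spur <- sum(!preceded)
  list(
    pct_successful = if (length(v) == 0) 0 else n_succ / length(v),
    pct_spurious = if (length(s) == 0) 0 else n_spur / length(s),
    n_successful = n_succ, n_value = length(v),
    n_spurious = n_spur, n_soma = length(s),
    undefined_successful = length(v) == 0,
    undefined_spurious = length(s) == 0)
}

#' One full match-and-control run
#'
#' Runs the match phase (query + 150 keys, one matched), converts raw scores
#' to potentiation factors through the calibrated threshold, the sigmoid and
#' the 500 ms lag (potentiation drive is taken to start at the match-window
#' midpoint, when roughly half the calcium evidence is in), waits out the
#' phase gap, then simulates the control phase with fresh value trains and
#' classifies the somatic output.
#'
#' @param window Match window, seconds.
#' @param value_window Control (value) window, seconds.
#' @param gap Silent gap between phases, seconds.
#' @param geometry A [build_geometry()] result.
#' @param params A [spine_params()] list.
#' @param calibration A [calibrate_threshold()] object (sets the threshold).
#' @param ctrl A [control_params()] list.
#' @param rate,refractory Poisson train parameters.
#' @param lag_tau Potentiation lag, seconds.
#' @param dt_ms Time step, ms.
#' @param seed Integer master seed for the run.
#' @return A `control_report` with the match-phase scores attached as
#'   attribute `match_scores`.
#' @export
run_match_control <- function(window = 1, value_window = 1, gap = 0.5,
                              geometry = build_geometry(),
                              params = spine_params(), calibration,
                              ctrl = control_params(), rate = 6,
                              refractory = 0.05, lag_tau = 0.5, dt_ms = 0.1,
                              seed = NULL) {
  run <- function() {
    soma <- sample_poisson_refractory(rate, refractory, window)
    ens <- gen_ensemble(soma, geometry, n_matched = 1,
                        rate = rate, refractory = refractory)
    scored <- score_ensemble(ens, soma, geometry, params, dt_ms = dt_ms)
    norm <- normalize_scores(scored$score, calibration)
    target <- potentiation_sigmoid(norm)
    elapsed <- window / 2 + gap
    factors <- lag_endpoint(1, target, elapsed, lag_tau)
    values <- lapply(seq_len(nrow(scored)), function(i) {
      sample_poisson_refractory(rate, refractory, value_window)
    })
    rep <- simulate_control(values, factors,
                            matched_index = attr(ens, "matched_index"),
                            ctrl = ctrl,
                            query_rate = n_spikes(soma) / window)
    attr(rep, "match_scores") <- scored$score
    attr(rep, "factors") <- factors
    rep
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
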