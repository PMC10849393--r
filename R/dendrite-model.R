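#' Dendritic tree geometry for the spine-group model
#'
#' Lays out `n_axons` spine groups (one axon synapsing `synapses_per_axon`
#' times on neighbouring spines) contiguously along `n_branches` tuft
#' branches, and assigns each group a BAP propagation latency that grows
#' linearly with distance along its branch.
#'
#' @param n_axons Number of axons / spine groups (default 150).
#' @param synapses_per_axon Synapses per axon, co-located (default 10).
#' @param n_branches Tuft branches (default 6).
#' @param latency_range Range of BAP arrival latencies along a branch, ms
#'   (default `c(0, 4)`).
#' @return A tibble of class `dendrite_geometry` with one row per spine group:
#'   `group`, `branch`, `position` (fraction along the branch) and
#'   `latency_ms`; attributes carry the counts.
#' @examples
#' g <- build_geometry()
#' attr(g, "n_spines") # 1500
#' @export
build_geometry <- function(n_axons = 150, synapses_per_axon = 10,
                           n_branches = 6, latency_range = c(0, 4)) {
  stopifnot(n_axons >= 1, synapses_per_axon >= 1, n_branches >= 1)
  if (n_axons %% n_branches != 0) {
    rlang::abort("n_axons must be divisible by n_branches for a contiguous layout")
  }
  per_branch <- n_axons / n_branches
  branch <- rep(seq_len(n_branches), each = per_branch)
  pos <- rep((seq_len(per_branch) - 0.5) / per_branch, times = n_branches)
  # symmetric branches tie-broken by a sub-microsecond branch offset
  lat <- latency_range[1] + pos * diff(latency_range) + (branch - 1) * 1e-4
  out <- tibble::tibble(group = seq_len(n_axons), branch = branch,
                        position = pos, latency_ms = lat)
  structure(out,
            class = c("dendrite_geometry", class(out)),
            n_axons = n_axons,
            synapses_per_axon = synapses_per_axon,
            n_branches = n_branches,
            n_spines = n_axons * synapses_per_axon,
            spines_per_branch = n_axons * synapses_per_axon / n_branches)
}

#' Parameters of the reduced spine model
#'
#' Closed-form surrogate of the spine biophysics: the somatic BAP arrives as a
#' brief depolarisation (difference-of-exponentials kernel), each presynaptic
#' spike adds an EPSP (scaled by the number of co-located synapses) and binds
#' glutamate to NMDA receptors (saturating two-exponential occupancy), the
#' extracellular-magnesium block gates calcium influx by spine voltage, and
#' spine calcium decays exponentially. The detector score is the time integral
#' of the fourth power of calcium.
#'
#' @param bap_amplitude BAP peak depolarisation at the spine, mV.
#' @param bap_rise,bap_decay BAP kernel time constants, ms.
#' @param epsp_amplitude EPSP peak per synapse, mV (a spine group feels
#'   `synapses_per_axon` times this).
#' @param epsp_rise,epsp_decay EPSP kernel time constants, ms.
#' @param nmda_rise,nmda_decay Glutamate-bound NMDA fraction kinetics, ms.
#' @param mg_conc Extracellular magnesium, mM.
#' @param mg_slope Voltage sensitivity of the magnesium block, 1/mV.
#' @param mg_k Magnesium block half-saturation constant, mM.
#' @param ca_decay Spine calcium decay time constant, ms.
#' @param noise_sd SD of the coloured membrane-potential noise, mV.
#' @param noise_corr_time Noise correlation time, ms.
#' @param resting_potential Resting potential, mV.
#' @param synapses_per_axon Synapses per spine group.
#' @return A list of class `spine_params`.
#' @export
spine_params <- function(bap_amplitude = 60, bap_rise = 0.2, bap_decay = 2,
                         epsp_amplitude = 0.85, epsp_rise = 0.5, epsp_decay = 5,
                         nmda_rise = 4.5, nmda_decay = 22,
                         mg_conc = 1, mg_slope = 0.062, mg_k = 3.57,
                         ca_decay = 15, noise_sd = 1, noise_corr_time = 5,
                         resting_potential = -70, synapses_per_axon = 10) {
  p <- as.list(environment())
  taus <- c(p$bap_rise, p$bap_decay, p$epsp_rise, p$epsp_decay,
            p$nmda_rise, p$nmda_decay, p$ca_decay, p$noise_corr_time)
  stopifnot(all(taus > 0), p$noise_sd >= 0, p$bap_rise < p$bap_decay,
            p$epsp_rise < p$epsp_decay, p$nmda_rise < p$nmda_decay)
  structure(p, class = "spine_params")
}

#' Spine-local BAP arrival times for one spine group
#'
#' Shifts every somatic spike by the group's propagation latency.
#'
#' @param soma Somatic [spike_train()].
#' @param geometry A [build_geometry()] result.
#' @param group Spine-group index.
#' @return A [spike_train()] whose duration is extended by the latency so all
#'   arrivals fit the window.
#' @export
bap_arrivals <- function(soma, geometry, group) {
  stopifnot(group >= 1, group <= attr(geometry, "n_axons"))
  lat_s <- geometry$latency_ms[geometry$group == group] / 1000
  spike_train(soma$times + lat_s, soma$duration + lat_s + 1e-9,
              label = soma$label)
}

#' Simulate one spine group
#'
#' Integrates the reduced spine model at time step `dt_ms` (exponential-Euler
#' for all gating and decay variables) and returns the voltage and calcium
#' traces plus the detector score.
#'
#' @param pre Presynaptic [spike_train()] (the key segment).
#' @param arrivals Spine-local BAP arrival [spike_train()].
#' @param params A [spine_params()] list.
#' @param dt_ms Time step in ms (default 0.1; > 0.5 is refused to protect the
#'   sub-millisecond kernel shapes).
#' @param duration Simulation window in seconds; defaults to the longer of the
#'   two input windows.
#' @param seed Optional integer seed for the membrane noise.
#' @param epsp_mult Multiplier on the EPSP amplitude (the potentiation factor
#'   during the control phase).
#' @return A tibble of class `spine_trace` with columns `time_ms`,
#'   `voltage_mV`, `calcium_au`; attribute `score` holds the detector
#'   integral and `dt_ms` the step.
#' @export
simulate_spine <- function(pre, arrivals, params = spine_params(),
                           dt_ms = 0.1, duration = NULL, seed = NULL,
                           epsp_mult = 1) {
  stopifnot(inherits(pre, "spike_train"), inherits(arrivals, "spike_train"),
            inherits(params, "spine_params"))
  if (dt_ms > 0.5) {
    rlang::abort("dt_ms > 0.5 ms is too coarse for the voltage kernels")
  }
  duration <- duration %||% max(pre$duration, arrivals$duration)
  n_steps <- as.integer(ceiling(duration * 1000 / dt_ms))
  run <- function() sim_spine_cpp(pre$times * 1000, arrivals$times * 1000,
                                  n_steps, dt_ms, unclass(params), epsp_mult)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- tibble::tibble(time_ms = (seq_len(n_steps) - 1) * dt_ms,
                        voltage_mV = res$voltage,
                        calcium_au = res$calcium)
  structure(out, class = c("spine_trace", class(out)),
            score = res$score, dt_ms = dt_ms)
}

#' Detector score: integral of the fourth power of calcium
#'
#' The similarity detector is deliberately non-linear: raising the calcium
#' concentration to the fourth power (the stoichiometry of calmodulin
#' activation) suppresses small leak events while keeping coincidence-driven
#' transients.
#'
#' @param ca A `spine_trace` (from [simulate_spine()]) or a numeric calcium
#'   vector.
#' @param dt_ms Time step in ms (taken from the trace when available).
#' @return The raw detector score, `sum(ca^4) * dt_ms` (arbitrary
#'   units^4 x ms).
#' @export
detector_integral <- function(ca, dt_ms = NULL) {
  if (inherits(ca, "spine_trace")) {
    dt_ms <- dt_ms %||% attr(ca, "dt_ms")
    ca <- ca$calcium_au
  }
  stopifnot(is.numeric(ca), all(is.finite(ca)), !is.null(dt_ms))
  sum(ca^4) * dt_ms
}
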