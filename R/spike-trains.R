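#' Construct a spike train
#'
#' A spike train is the universal carrier of queries, keys and values in the
#' match-and-control scheme: a strictly increasing vector of spike times on a
#' finite window.
#'
#' @param times Numeric vector of spike times in seconds, within
#'   `[0, duration)`. Sorted on construction; duplicates are an error.
#' @param duration Window length in seconds (> 0).
#' @param label Optional free-text label.
#' @param refractory Minimum inter-spike interval the generator enforced, in
#'   seconds (metadata; `NA` when unknown).
#' @return An object of class `spike_train`.
#' @examples
#' spike_train(c(0.1, 0.35), duration = 1)
#' @export
spike_train <- function(times, duration, label = NULL, refractory = NA_real_) {
  times <- as.numeric(times)
  stopifnot(is.numeric(duration), length(duration) == 1, duration > 0)
  times <- sort(times)
  if (length(times) > 0) {
    if (any(times < 0) || any(times >= duration)) {
      rlang::abort("spike times must lie in [0, duration)")
    }
    if (any(diff(times) <= 0)) {
      rlang::abort("spike times must be strictly increasing")
    }
  }
  structure(
    list(times = times, duration = duration, label = label,
         refractory = refractory),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.3g s", length(x$times), x$duration))
  if (!is.null(x$label)) cat(" [", x$label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @rdname spike_train
#' @param x A `spike_train`.
#' @export
n_spikes <- function(x) length(x$times)

#' Sample a Poisson spike train with a refractory dead time
#'
#' Inter-spike intervals are `refractory + Exp(rate_base)`. By default the
#' base rate is inflated to `rate / (1 - rate * refractory)` so the realized
#' long-run rate equals the nominal `rate` (dead-time compensation); set
#' `compensate = FALSE` to use `rate` as the bare exponential rate instead.
#'
#' @param rate Nominal mean firing rate in Hz (>= 0).
#' @param refractory Dead time in seconds (>= 0).
#' @param duration Window length in seconds (> 0).
#' @param seed Optional integer seed (applied locally; the global RNG state is
#'   restored afterwards).
#' @param compensate Compensate the base rate for the dead time (default).
#' @param label Optional label.
#' @return A [spike_train()].
#' @examples
#' sample_poisson_refractory(6, 0.05, 1, seed = 1)
#' @export
sample_poisson_refractory <- function(rate, refractory, duration, seed = NULL,
                                      compensate = TRUE, label = NULL) {
  stopifnot(rate >= 0, refractory >= 0, duration > 0)
  if (rate == 0) {
    return(spike_train(numeric(0), duration, label, refractory))
  }
  if (compensate && rate * refractory >= 1) {
    rlang::abort(sprintf(
      "nominal rate %g Hz is unreachable with a %g s dead time (rate * refractory >= 1)",
      rate, refractory))
  }
  base_rate <- if (compensate) rate / (1 - rate * refractory) else rate
  draw <- function() {
    # draw gaps in blocks until the window is covered
    t <- numeric(0)
    last <- 0
    repeat {
      k <- max(16L, ceiling((duration - last) * base_rate * 1.5))
      gaps <- refractory + stats::rexp(k, base_rate)
      tt <- last + cumsum(gaps)
      t <- c(t, tt)
      last <- t[length(t)]
      if (last >= duration) break
    }
    t[t < duration]
  }
  times <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  spike_train(times, duration, label, refractory)
}

#' Build the matched presynaptic train for a set of BAP arrivals
#'
#' Places one presynaptic spike `lead` seconds before each spine-local
#' back-propagating action potential (BAP) arrival. Arrivals earlier than
#' `lead` are dropped.
#'
#' @param post_arrivals A [spike_train()] of spine-local BAP arrival times.
#' @param lead Lead time in seconds (default 0.007: presynaptic spikes arrive
#'   7 ms before the BAP, the detector's optimum).
#' @return A [spike_train()] on the same window.
#' @export
make_matched_train <- function(post_arrivals, lead = 0.007) {
  stopifnot(inherits(post_arrivals, "spike_train"), lead >= 0)
  t <- post_arrivals$times - lead
  spike_train(t[t >= 0], post_arrivals$duration, label = "matched")
}

#' Jitter spike times with Gaussian noise
#'
#' Each spike is shifted independently by `N(0, sigma^2)`; the result is
#' re-sorted and clipped to the window boundaries (not wrapped). Refractory
#' violations introduced by the jitter are allowed.
#'
#' @param train A [spike_train()].
#' @param sigma Jitter SD in seconds (>= 0).
#' @param seed Optional integer seed.
#' @return A [spike_train()].
#' @export
jitter_train <- function(train, sigma, seed = NULL) {
  stopifnot(inherits(train, "spike_train"), sigma >= 0)
  if (sigma == 0 || n_spikes(train) == 0) return(train)
  draw <- function() train$times + stats::rnorm(n_spikes(train), 0, sigma)
  t <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  t <- pmin(pmax(t, 0), train$duration - 1e-9)
  t <- sort(t)
  # collapse numerically coincident spikes created by boundary clipping
  if (length(t) > 1) t <- t[c(TRUE, diff(t) > 0)]
  spike_train(t, train$duration, train$label, NA_real_)
}

#' Concatenate a key phase and a value phase into one axonal train
#'
#' Keys and values travel down the same axon, temporally concatenated: the
#' value segment is offset by the key duration plus a silent gap.
#'
#' @param key,value [spike_train()]s on their own windows.
#' @param gap Silent gap in seconds between the phases (default 0.5).
#' @return A [spike_train()] of duration `key$duration + gap + value$duration`.
#' @export
concatenate_phases <- function(key, value, gap = 0.5) {
  stopifnot(inherits(key, "spike_train"), inherits(value, "spike_train"), gap >= 0)
  off <- key$duration + gap
  spike_train(c(key$times, value$times + off),
              key$duration + gap + value$duration,
              label = key$label)
}

#' Generate an ensemble of axonal key trains
#'
#' Draws one train per axon (149 random + up to 2 matched by default
#' geometry). Matched axons receive one presynaptic spike 7 ms before each of
#' their spine group's BAP arrivals, optionally jittered.
#'
#' @param soma Somatic [spike_train()] (the query) driving the BAPs.
#' @param geometry A [build_geometry()] result (supplies per-group BAP
#'   latencies).
#' @param n_matched Number of matched axons: 0, 1 or 2.
#' @param matched_index Indices of the matched axons; defaults to a random
#'   draw.
#' @param rate,refractory Poisson parameters of the random (key) trains.
#' @param lead Matched-train lead time in seconds.
#' @param jitter_sd Gaussian jitter SD (seconds) applied to matched trains.
#' @param seed Integer master seed; the whole ensemble is drawn under it.
#' @return A tibble of class `train_ensemble` with columns `axon`, `matched`
#'   and list-column `train`, plus attributes `window` and `matched_index`.
#' @export
gen_ensemble <- function(soma, geometry, n_matched = 1, matched_index = NULL,
                         rate = 6, refractory = 0.05, lead = 0.007,
                         jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(soma, "spike_train"), n_matched %in% 0:2)
  n_axons <- attr(geometry, "n_axons")
  build <- function() {
    idx <- matched_index %||% (if (n_matched > 0) sample.int(n_axons, n_matched) else integer(0))
    trains <- vector("list", n_axons)
    for (i in seq_len(n_axons)) {
      if (i %in% idx) {
        tr <- make_matched_train(bap_arrivals(soma, geometry, i), lead)
        if (jitter_sd > 0) tr <- jitter_train(tr, jitter_sd)
        trains[[i]] <- tr
      } else {
        trains[[i]] <- sample_poisson_refractory(rate, refractory, soma$duration)
      }
    }
    list(trains = trains, idx = sort(idx))
  }
  res <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  out <- tibble::tibble(
    axon = seq_len(n_axons),
    matched = seq_len(n_axons) %in% res$idx,
    train = res$trains
  )
  structure(out,
            class = c("train_ensemble", class(out)),
            window = soma$duration,
            matched_index = res$idx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read spike trains as CSV with a JSON sidecar
#'
#' The CSV holds `(train_id, spike_time_s)` rows at microsecond-lossless
#' precision; the JSON sidecar (same path with `.json` appended) carries
#' durations, labels and the matched indices, so a round trip is lossless.
#'
#' @param trains A named or unnamed list of [spike_train()]s, or a
#'   `train_ensemble`.
#' @param path CSV file path.
#' @param matched_index Optional integer vector recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(trains, path, matched_index = integer(0)) {
  if (inherits(trains, "train_ensemble")) {
    matched_index <- attr(trains, "matched_index")
    trains <- trains$train
  }
  stopifnot(all(vapply(trains, inherits, logical(1), "spike_train")))
  ids <- names(trains) %||% as.character(seq_along(trains))
  df <- purrr::map2_dfr(trains, ids, function(tr, id) {
    tibble::tibble(train_id = id,
                   spike_time_s = sprintf("%.9f", tr$times))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(
    train_id = ids,
    duration_s = vapply(trains, function(tr) tr$duration, numeric(1)),
    label = vapply(trains, function(tr) tr$label %||% "", character(1)),
    matched_index = as.integer(matched_index)
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  trains <- purrr::pmap(
    list(side$train_id, side$duration_s, side$label),
    function(id, dur, lab) {
      t <- df$spike_time_s[df$train_id == id]
      spike_train(t, dur, if (nzchar(lab)) lab else NULL)
    })
  names(trains) <- side$train_id
  attr(trains, "matched_index") <- side$matched_index
  trains
}
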