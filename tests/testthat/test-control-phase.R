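test_that("potentiation sigmoid hits its printed endpoints", {
  expect_equal(potentiation_sigmoid(0), 1, tolerance = 0.05)
  expect_equal(potentiation_sigmoid(2), 8, tolerance = 0.05 / 8)
  expect_equal(potentiation_sigmoid(0.92), 4.5)
  # monotone
  s <- potentiation_sigmoid(seq(0, 2, by = 0.01))
  expect_false(is.unsorted(s))
  expect_error(potentiation_sigmoid(-0.1))
})

test_that("lag is a first-order low-pass with the exact step response", {
  dt <- 0.001
  n <- 500 # 0.5 s
  f <- apply_lag(rep(8, n), lag_tau = 0.5, dt = dt)
  expect_equal(f[n], 1 + 7 * (1 - exp(-1)), tolerance = 1e-6)
  # constant target 1 stays at 1
  expect_equal(apply_lag(rep(1, 100), 0.5, dt), rep(1, 100))
  # short lag tracks the target closely
  f2 <- apply_lag(rep(8, 200), lag_tau = 0.02, dt = dt)
  expect_equal(f2[200], 8, tolerance = 1e-4)
})

test_that("spike classification follows the 20 ms window rules", {
  w1 <- spike_train(c(1.0, 1.5), 2)
  s1 <- spike_train(c(1.005, 1.510), 2)
  c1 <- classify_spikes(s1, w1)
  expect_equal(c1$pct_successful, 1)
  expect_equal(c1$pct_spurious, 0)

  c2 <- classify_spikes(spike_train(1.5, 2), spike_train(1.0, 2))
  expect_equal(c2$pct_successful, 0)
  expect_equal(c2$pct_spurious, 1)

  # greedy one-to-one hand count
  c3 <- classify_spikes(spike_train(c(1.01, 1.9), 2),
                        spike_train(c(1.0, 1.2, 1.4), 2))
  expect_equal(c3$pct_successful, 1 / 3)
  expect_equal(c3$pct_spurious, 1 / 2)

  # 0/0 conventions carry explicit flags
  c4 <- classify_spikes(spike_train(numeric(0), 1), spike_train(numeric(0), 1))
  expect_equal(c4$pct_successful, 0)
  expect_true(c4$undefined_successful)
  expect_true(c4$undefined_spurious)
})

test_that("control phase relays potentiated axons and only those", {
  vals <- list(spike_train(c(0.1, 0.4, 0.7), 1),
               spike_train(c(0.2, 0.5), 1),
               spike_train(c(0.3, 0.8), 1))
  ctrl <- control_params(p_success = 1, spurious_rate = 0)
  # no potentiated axon, zero noise -> silent soma, 0/0 reported as 0
  r0 <- simulate_control(vals, c(1, 1, 1), matched_index = 1, ctrl = ctrl,
                         seed = 1)
  expect_equal(n_spikes(r0$soma_spikes), 0)
  expect_equal(r0$pct_spurious, 0)
  expect_true(r0$undefined_spurious)

  # one fully potentiated axon, deterministic relay
  r1 <- simulate_control(vals, c(8, 1, 1), matched_index = 1, ctrl = ctrl,
                         seed = 1)
  expect_equal(r1$soma_spikes$times, vals[[1]]$times + ctrl$latency)
  expect_equal(r1$pct_successful, 1)
  expect_equal(r1$pct_spurious, 0)

  # two potentiated axons -> union of value trains (set-union oracle)
  r2 <- simulate_control(vals, c(8, 8, 1), matched_index = c(1, 2),
                         ctrl = ctrl, seed = 1)
  expect_equal(r2$soma_spikes$times,
               sort(c(vals[[1]]$times, vals[[2]]$times)) + ctrl$latency)

  # somatic refractoriness collapses near-coincident relays
  close_vals <- list(spike_train(c(0.1), 1), spike_train(c(0.101), 1))
  r3 <- simulate_control(close_vals, c(8, 8), matched_index = 1, ctrl = ctrl,
                         seed = 1)
  expect_equal(n_spikes(r3$soma_spikes), 1)
})

test_that("threshold sweep shows more somatic spikes at lower thresholds", {
  # factors come from the sigmoid of score/threshold: sweeping the threshold
  # downward potentiates more axons and monotonically increases output,
  # with a runaway regime when nearly everything potentiates
  withr::with_seed(13, {
    scores <- rexp(150, 1 / 50)
    scores[1] <- 400
    vals <- purrr::map(1:150, function(i) sample_poisson_refractory(6, 0.05, 1))
  })
  ctrl <- control_params(p_success = 1, spurious_rate = 0)
  counts <- vapply(c(1000, 300, 100, 20, 5), function(thr) {
    f <- potentiation_sigmoid(scores / thr)
    r <- simulate_control(vals, f, matched_index = 1, ctrl = ctrl, seed = 2)
    n_spikes(r$soma_spikes)
  }, numeric(1))
  expect_false(is.unsorted(counts))
  # runaway: the lowest threshold fires at least an order of magnitude more
  # than the highest
  expect_gt(counts[5], 10 * max(1, counts[1]))
})

test_that("continued potentiation during control only grows the factors", {
  vals <- list(sample_poisson_refractory(6, 0.05, 1, seed = 41),
               sample_poisson_refractory(6, 0.05, 1, seed = 42))
  f0 <- c(2.5, 3.0) # two weakly potentiated (sub-relay) axons
  r <- simulate_control(vals, f0, matched_index = 1,
                        ctrl = control_params(spurious_rate = 0), seed = 3,
                        continue_potentiation = TRUE,
                        norm_scores = c(0.8, 0.85), threshold = 100,
                        spine_par = quiet_params())
  expect_true(all(r$factors_end >= f0))
  expect_gt(sum(r$factors_end - f0), 0)
})

test_that("full match-and-control run relays a strong match", {
  g <- tiny_geometry()
  p <- quiet_params()
  cal <- suppressWarnings(calibrate_threshold(rep(60, 50), window = 0.5))
  rep <- run_match_control(window = 0.5, value_window = 0.5, geometry = g,
                           params = p, calibration = cal,
                           ctrl = control_params(p_success = 1,
                                                 spurious_rate = 0),
                           seed = 17)
  expect_s3_class(rep, "control_report")
  expect_true(rep$pct_successful >= 0 && rep$pct_successful <= 1)
  expect_true(rep$pct_spurious >= 0 && rep$pct_spurious <= 1)
  expect_equal(length(attr(rep, "factors")), attr(g, "n_axons"))
})

test_that("control-phase success grows with match window and query rate", {
  g <- tiny_geometry(30, 6)
  p <- spine_params()
  succ <- list()
  rate_effect <- NULL
  for (w in c(0.5, 1, 2)) {
    cal <- calibrate_threshold(run_null_batch(120, w, g, p, n_null = 30,
                                              seed = 81 + w),
                               window = w)
    reps <- purrr::map(1:50, function(r) {
      run_match_control(window = w, value_window = 1, geometry = g,
                        params = p, calibration = cal, seed = 9000 + r)
    })
    succ[[as.character(w)]] <- vapply(reps, `[[`, numeric(1), "pct_successful")
    if (w == 0.5) {
      qr <- vapply(reps, `[[`, numeric(1), "query_rate")
      s <- succ[["0.5"]]
      rate_effect <- mean(s[qr > stats::median(qr)]) -
        mean(s[qr <= stats::median(qr)])
    }
  }
  m <- vapply(succ, mean, numeric(1))
  # success percentage monotone non-decreasing in window length
  expect_true(m[["0.5"]] <= m[["1"]] && m[["1"]] <= m[["2"]])
  expect_gt(m[["2"]], m[["0.5"]])
  # higher query spike rate helps at the short window
  expect_gt(rate_effect, 0)
})
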