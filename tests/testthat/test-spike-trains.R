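test_that("spike_train validates its invariants", {
  expect_error(spike_train(c(0.5, 0.5), 1), "strictly increasing")
  expect_error(spike_train(c(-0.1), 1), "0, duration")
  expect_error(spike_train(c(1.0), 1), "0, duration")
  tr <- spike_train(c(0.3, 0.1), 1) # sorted on construction
  expect_equal(tr$times, c(0.1, 0.3))
})

test_that("poisson sampler respects rate, refractoriness and edge cases", {
  expect_equal(n_spikes(sample_poisson_refractory(0, 0.05, 1, seed = 1)), 0)
  expect_lte(n_spikes(sample_poisson_refractory(6, 0.05, 0.05, seed = 7)), 1)
  expect_error(sample_poisson_refractory(21, 0.05, 1), "unreachable")

  # refractory invariant over several seeds
  for (s in 1:10) {
    tr <- sample_poisson_refractory(6, 0.05, 5, seed = s)
    expect_true(all(diff(tr$times) >= 0.05))
    expect_true(all(tr$times >= 0 & tr$times < 5))
  }

  # dead-time-compensated realized rate at long duration (law of large numbers)
  tr <- sample_poisson_refractory(6, 0.05, 1000, seed = 3)
  expect_equal(n_spikes(tr) / 1000, 6, tolerance = 0.1 / 6)

  # uncompensated variant runs slower than nominal
  tr2 <- sample_poisson_refractory(6, 0.05, 1000, seed = 3, compensate = FALSE)
  expect_lt(n_spikes(tr2) / 1000, 5.2)
})

test_that("matched-train construction shifts and drops correctly", {
  arr <- spike_train(c(0.100, 0.300), 1)
  expect_equal(make_matched_train(arr)$times, c(0.093, 0.293))
  expect_equal(n_spikes(make_matched_train(spike_train(numeric(0), 1))), 0)
  expect_equal(n_spikes(make_matched_train(spike_train(0.005, 1), 0.007)), 0)
})

test_that("jitter is identity at sigma 0, Gaussian otherwise, and keeps order", {
  tr <- spike_train(c(0.1, 0.2), 1)
  expect_identical(jitter_train(tr, 0), tr)
  j <- jitter_train(tr, 0.002, seed = 1)
  expect_equal(n_spikes(j), 2)
  expect_false(is.unsorted(j$times))
  expect_true(all(j$times >= 0 & j$times < 1))

  # Monte-Carlo SD of a single jittered spike matches the nominal sigma
  single <- spike_train(0.5, 1)
  shifted <- vapply(1:400, function(s) jitter_train(single, 0.001, seed = s)$times,
                    numeric(1))
  expect_equal(sd(shifted), 0.001, tolerance = 0.15)
})

test_that("phase concatenation offsets the value by key duration plus gap", {
  key <- spike_train(0.1, 1)
  val <- spike_train(0.2, 1)
  out <- concatenate_phases(key, val, gap = 0.5)
  expect_equal(out$times, c(0.1, 1.7))
  expect_equal(out$duration, 2.5)
  out0 <- concatenate_phases(key, val, gap = 0)
  expect_equal(out0$times, c(0.1, 1.2))
  # empty value: key padded to the full window
  oute <- concatenate_phases(key, spike_train(numeric(0), 1))
  expect_equal(oute$times, 0.1)
  expect_equal(oute$duration, 2.5)
})

test_that("ensembles have the right shape and matched construction", {
  g <- tiny_geometry()
  soma <- sample_poisson_refractory(6, 0.05, 1, seed = 4)
  ens <- gen_ensemble(soma, g, n_matched = 1, seed = 9)
  expect_s3_class(ens, "train_ensemble")
  expect_equal(nrow(ens), 6)
  expect_equal(sum(ens$matched), 1)
  idx <- attr(ens, "matched_index")
  # matched train leads the group's BAP arrivals by 7 ms
  arr <- bap_arrivals(soma, g, idx)
  expect_equal(ens$train[[idx]]$times, make_matched_train(arr)$times)
  # 0 and 2 matched axons are allowed, 3 are not
  expect_equal(sum(gen_ensemble(soma, g, n_matched = 0, seed = 1)$matched), 0)
  expect_equal(sum(gen_ensemble(soma, g, n_matched = 2, seed = 1)$matched), 2)
  expect_error(gen_ensemble(soma, g, n_matched = 3, seed = 1))
})

test_that("spike-train CSV + sidecar round-trip is lossless to 1 microsecond", {
  g <- tiny_geometry()
  soma <- sample_poisson_refractory(6, 0.05, 1, seed = 5)
  ens <- gen_ensemble(soma, g, n_matched = 1, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spike_trains(ens, path)
  back <- read_spike_trains(path)
  expect_equal(length(back), 6)
  expect_equal(attr(back, "matched_index"), attr(ens, "matched_index"))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$times, ens$train[[i]]$times, tolerance = 1e-7)
    expect_equal(back[[i]]$duration, ens$train[[i]]$duration)
  }
})
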