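test_that("kernel envelope decays exponentially (tau 10 ms) beyond 30 ms", {
  # asymptotic decay ratio e^{-dt/10} well outside the window
  t <- seq(80, 130, by = 5)
  env <- kernel_envelope(t)
  ratio <- env[-1] / env[-length(env)]
  expect_equal(ratio, rep(exp(-5 / 10), length(ratio)), tolerance = 0.01)
  # strictly decreasing beyond the window edge, and already down ~e^-2 by 50 ms
  t2 <- seq(30, 120, by = 1)
  expect_true(all(diff(kernel_envelope(t2)) < 0))
  expect_lt(kernel_envelope(50), 0.15)
  expect_equal(kernel_envelope(0), kernel_envelope(0)) # symmetric centre
  expect_equal(kernel_envelope(-45), kernel_envelope(45))
})

test_that("bilinear model equals the brute-force pairwise oracle", {
  k <- bump_kernel()
  empty <- spike_train(numeric(0), 1)
  expect_equal(predict_kernel_model(k, empty, spike_train(0.5, 1)), 0)
  # single pair at the 7 ms difference evaluates K(7)
  expect_equal(predict_kernel_model(k, spike_train(0.1, 1), spike_train(0.107, 1)),
               eval_kernel(k, 7))
  # random small trains vs O(n^2) summation, many cases
  withr::with_seed(5, {
    for (i in 1:20) {
      pre <- sample_poisson_refractory(8, 0.01, 1)
      post <- sample_poisson_refractory(8, 0.01, 1)
      expect_equal(predict_kernel_model(k, pre, post),
                   brute_overlap(k, pre, post))
    }
  })
  # superposition in the presynaptic argument
  a <- spike_train(c(0.1, 0.4), 1); b <- spike_train(c(0.2, 0.6), 1)
  ab <- spike_train(sort(c(a$times, b$times)), 1)
  post <- spike_train(c(0.15, 0.45), 1)
  expect_equal(predict_kernel_model(k, ab, post),
               predict_kernel_model(k, a, post) + predict_kernel_model(k, b, post))
})

test_that("a delta-like kernel reduces the model to a binned inner product", {
  # 1-ms-wide triangle at lag 0 ~ counts coincidences in the same 1 ms bin
  grid <- seq(-50, 50, by = 1)
  interior <- as.numeric(grid == 0) / kernel_envelope(0)
  k <- make_kernel(grid, interior)
  pre <- spike_train(c(0.100, 0.250, 0.600), 1)
  post <- spike_train(c(0.100, 0.250, 0.480), 1)
  # two exact coincidences -> inner product 2
  expect_equal(predict_kernel_model(k, pre, post), 2)
})

test_that("outlier removal matches brute-force order statistics", {
  expect_equal(remove_outliers(c(1, 1, 1, 1))$n_removed, 0)
  x <- c(rep(0, 999), 100)
  r <- remove_outliers(x)
  expect_equal(r$n_removed, 1)
  expect_false(100 %in% r$kept)
  # brute-force check of the rule on random data
  withr::with_seed(2, {
    y <- c(rnorm(500), 25)
    keep_oracle <- y <= mean(y) + 4 * sd(y)
    expect_equal(remove_outliers(y)$keep, keep_oracle)
  })
  expect_equal(remove_outliers(c(rnorm(50), 100), k_sd = Inf)$n_removed, 0)
})

test_that("kernel fit recovers a planted kernel and scales linearly", {
  k0 <- bump_kernel()
  withr::with_seed(11, {
    ds <- purrr::map_dfr(1:60, function(s) {
      post <- sample_poisson_refractory(6, 0.05, 1)
      purrr::map_dfr(1:12, function(a) {
        pre <- sample_poisson_refractory(6, 0.05, 1)
        sc <- predict_kernel_model(k0, pre, post)
        tibble::tibble(sim = s, axon = a, pre = list(pre), post = list(post),
                       score = sc)
      })
    })
    sigma <- 0.05 * sd(ds$score)
    ds$score <- ds$score + rnorm(nrow(ds), 0, sigma)
  })
  fit <- fit_kernel(ds, seed = 3)
  # recovery within 10% RMS of the planted kernel, on the effective region
  reg <- abs(k0$dt_ms) <= 35
  rms_err <- sqrt(mean((fit$kernel$value[reg] - k0$value[reg])^2))
  expect_lt(rms_err / sqrt(mean(k0$value[reg]^2)), 0.10)
  expect_gt(fit$r2_test, 0.9)

  # doubling all scores doubles the fitted kernel
  ds2 <- dplyr::mutate(ds, score = 2 * score)
  fit2 <- fit_kernel(ds2, seed = 3)
  expect_equal(fit2$kernel$value, 2 * fit$kernel$value, tolerance = 1e-6)

  # degenerate all-zero dataset yields the zero kernel, flagged
  ds0 <- dplyr::mutate(ds, score = 0)
  fit0 <- fit_kernel(ds0, seed = 3)
  expect_true(fit0$degenerate)
  expect_equal(max(abs(fit0$kernel$value)), 0)
})

test_that("ensemble scoring is deterministic, equivariant and zero on empties", {
  g <- tiny_geometry()
  p <- quiet_params()
  soma <- sample_poisson_refractory(6, 0.05, 0.5, seed = 21)
  ens <- gen_ensemble(soma, g, n_matched = 1, seed = 22)
  s1 <- score_ensemble(ens, soma, g, p, seed = 1)
  s2 <- score_ensemble(ens, soma, g, p, seed = 1)
  expect_identical(s1$score, s2$score)
  # matched axon wins in this noiseless draw
  expect_equal(which.max(s1$score), attr(ens, "matched_index"))
  # all-empty axon trains with no noise score exactly zero
  ens0 <- ens
  ens0$train <- purrr::map(ens0$train, function(tr) spike_train(numeric(0), 0.5))
  expect_equal(score_ensemble(ens0, soma, g, p)$score, rep(0, nrow(ens0)))
  # permuting axon order permutes scores identically (same seed, no noise)
  perm <- rev(seq_len(nrow(ens)))
  ensp <- ens[perm, ]
  attr(ensp, "window") <- attr(ens, "window")
  class(ensp) <- class(ens)
  sp <- score_ensemble(ensp, soma, g[perm, ], p)
  expect_equal(sp$score, s1$score[perm])
})

test_that("offset sweep is deterministic without noise and peaks near 7 ms", {
  p <- quiet_params()
  sw1 <- offset_sweep(c(0, 7, 30), reps = 1, window = 0.5, params = p, seed = 1)
  sw2 <- offset_sweep(c(0, 7, 30), reps = 1, window = 0.5, params = p, seed = 1)
  expect_equal(sw1$mean_score, sw2$mean_score)
  sw <- offset_sweep(seq(-5, 25, by = 2), reps = 15, window = 0.5, params = p,
                     seed = 5)
  peak <- sw$offset_ms[which.max(sw$mean_score)]
  expect_gte(peak, 2)
  expect_lte(peak, 12)
  # far-offset scores sit at the curve floor (glutamate-leak level, no
  # coincidence): +100 ms matches the pre-after-BAP floor at -15 ms
  far <- offset_sweep(c(-15, 7, 100), reps = 10, window = 0.5, params = p,
                      seed = 6)
  expect_lt(abs(far$mean_score[3] - far$mean_score[1]) / far$mean_score[2], 0.1)
})
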