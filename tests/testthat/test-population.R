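# Tuning curves, best frequency, off-BF selectivity, noise correlations.

grid10 <- 2 * 2^((0:9) / 2)

test_that("tuning curves peak at the driven frequency, ties to the lowest", {
  freqs <- rep(grid10, each = 2)
  amp <- matrix(0, 2, length(freqs))
  amp[1, freqs == 8] <- 1
  amp[2, freqs %in% c(8, 8 * sqrt(2))] <- 1  # exact tie at 8 and 11.31
  ftc <- tuning_curve(amp, freqs, grid10)
  expect_equal(ftc$bf_khz, c(8, 8))
  expect_error(tuning_curve(amp[, freqs != 8], freqs[freqs != 8], grid10),
               "at least one trial")
})

test_that("noiseless generator neurons recover their true BF", {
  fx <- tiny_experiment()
  tr <- neuropil_correct(fx$exper$traces)
  tens <- sigma_normalize(compute_dff(tr, fx$proto))
  ftc <- tuning_curve(response_amplitude(tens), tens$trial_frequencies,
                      fx$proto$frequencies_khz)
  expect_equal(ftc$bf_khz, fx$exper$truth$bf_khz)
})

test_that("peak normalization scales the maximum to one", {
  ftc <- tuning_curve(rbind(c(0.2, 0.4), c(0.3, 0.3)), c(4, 8), c(4, 8))
  pn <- peak_normalize(ftc)
  expect_equal(pn$response[1, ], c(0.5, 1), ignore_attr = TRUE)
  expect_identical(peak_normalize(pn)$response, pn$response)
  bad <- tuning_curve(rbind(c(-1, -2), c(1, 2)), c(4, 8), c(4, 8))
  expect_warning(pnb <- peak_normalize(bad), "nonpositive FTC peak")
  expect_identical(pnb$neurons_kept, 2L)
})

test_that("group-averaged FTCs reproduce single members and shared shapes", {
  freqs <- rep(grid10, each = 2)
  # one neuron alone in its BF group: group curve equals its own curve
  amp1 <- rbind(tuning_weight_vec <- exp(-(log2(freqs) - 3)^2 / 2))
  ftc1 <- peak_normalize(tuning_curve(amp1, freqs, grid10))
  g1 <- group_average_ftc(ftc1)
  expect_equal(g1$mean, as.vector(ftc1$response[1, ]), tolerance = 1e-12)
  # two identical neurons: SEM exactly zero
  ftc2 <- peak_normalize(tuning_curve(rbind(amp1, amp1), freqs, grid10))
  g2 <- group_average_ftc(ftc2)
  expect_true(all(g2$sem == 0))
  expect_equal(unique(g2$n_neurons), 2L)
  # noiseless Gaussian cohort: group curve matches exp(-d^2 / 2w^2)
  fx <- tiny_experiment()
  tr <- neuropil_correct(fx$exper$traces)
  tens <- sigma_normalize(compute_dff(tr, fx$proto))
  ftc <- peak_normalize(tuning_curve(response_amplitude(tens),
                                     tens$trial_frequencies,
                                     fx$proto$frequencies_khz))
  g <- group_average_ftc(ftc)
  expected <- exp(-(log2(g$frequency_khz) - log2(g$bf_khz))^2 / 2)
  expect_equal(g$mean, expected, tolerance = 1e-9)
})

test_that("off-BF percentage follows its closed form", {
  flat <- tuning_curve(rbind(rep(2, 20)), rep(grid10, 2), grid10)
  expect_equal(off_bf_ratio(flat), 100)
  solo <- matrix(0, 1, 20); solo[1, rep(grid10, 2) == 8] <- 1
  expect_equal(off_bf_ratio(tuning_curve(solo, rep(grid10, 2), grid10)), 0)
  # Gaussian tuning, width w, BF 8 kHz on the 10-tone grid
  w <- 0.8
  resp <- exp(-(log2(grid10) - 3)^2 / (2 * w^2))
  ftc <- tuning_curve(rbind(resp[rep(1:10, each = 2)]),
                      rep(grid10, each = 2), grid10)
  expect_equal(off_bf_ratio(ftc),
               100 * mean(exp(-(log2(grid10[grid10 != 8]) - 3)^2 /
                                (2 * w^2))),
               tolerance = 1e-9)
  neg <- tuning_curve(rbind(c(-1, -2)), c(4, 8), c(4, 8))
  expect_warning(r <- off_bf_ratio(neg), "nonpositive BF response")
  expect_true(is.na(r))
})

test_that("noise correlations match a brute-force double-loop oracle", {
  set.seed(14)
  freqs <- rep(c(4, 8, 16), each = 4)
  amp <- matrix(rnorm(5 * 12), 5, 12) + outer(runif(5), freqs / 10)
  nc <- noise_correlations(amp, freqs)
  # oracle: residuals and pairwise cor computed element by element
  resid <- amp
  for (i in 1:5) for (fq in unique(freqs)) {
    cols <- freqs == fq
    resid[i, cols] <- amp[i, cols] - mean(amp[i, cols])
  }
  vals <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    r <- cor(resid[i, ], resid[j, ])
    expect_equal(nc$pair_matrix[i, j], r, tolerance = 1e-12)
    vals <- c(vals, r)
  }
  expect_equal(nc$experiment_mean, mean(vals), tolerance = 1e-12)
})

test_that("noise-correlation matrix invariants hold", {
  set.seed(15)
  freqs <- rep(grid10, each = 3)
  amp <- matrix(rnorm(6 * 30), 6, 30)
  nc <- noise_correlations(amp, freqs)
  expect_equal(nc$pair_matrix, t(nc$pair_matrix))
  expect_equal(diag(nc$pair_matrix), rep(1, 6))
  expect_true(all(abs(nc$pair_matrix) <= 1 + 1e-12))
  # duplicate neuron: perfect pair correlation
  nc2 <- noise_correlations(rbind(amp[1, ], amp[1, ] * 2 + 3, amp[2, ]),
                            freqs)
  expect_equal(nc2$pair_matrix[1, 2], 1, tolerance = 1e-12)
  # invariance to per-neuron affine rescaling
  scaled <- amp * runif(6, 0.5, 3) + rnorm(6)
  nc3 <- noise_correlations(scaled, freqs)
  expect_equal(nc3$pair_matrix, nc$pair_matrix, tolerance = 1e-9)
})

test_that("zero-variance neurons make their pairs NA with a warning", {
  freqs <- rep(c(4, 8), each = 3)
  amp <- rbind(rnorm(6), rep(c(1, 2), each = 3), rnorm(6))
  expect_warning(nc <- noise_correlations(amp, freqs), "zero residual")
  expect_true(all(is.na(nc$pair_matrix[2, ])))
  expect_false(is.na(nc$experiment_mean))
  expect_error(noise_correlations(amp[1, , drop = FALSE], freqs), ">= 2")
  expect_error(noise_correlations(amp[, c(1, 4)], c(4, 8)), ">= 2 trials")
})

test_that("estimated noise correlation is monotone in the generator rho", {
  proto <- make_tone_protocol(seed = 41)
  est <- vapply(c(0, 0.1, 0.3, 0.5), function(rho) {
    cfg <- synth_neural_config(n_neurons = 30, shared_noise_rho = rho,
                               trial_noise_sd = 0.2,
                               seed = 50 + round(100 * rho))
    amp <- simulate_trial_amplitudes(cfg, proto, 1)
    noise_correlations(amp, proto$trials$frequency_khz)$experiment_mean
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
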