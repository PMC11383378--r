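# Frame differencing, movement energy, Hilbert envelope, spatial maps,
# window means, and head-twitch template correlation.

test_that("frame differences are signed, length n-1, and antisymmetric", {
  static <- array(2, c(8, 8, 5))
  expect_true(all(frame_difference(static)$vprime == 0))
  v <- array(0, c(4, 4, 4))
  v[2, 3, ] <- 0:3  # one pixel stepping +1 per frame
  fd <- frame_difference(v)
  expect_equal(dim(fd$vprime)[3], 3)
  expect_true(all(fd$vprime[2, 3, ] == 1))
  expect_true(all(fd$vprime[-2, , ] == 0))
  rev_fd <- frame_difference(v[, , 4:1])
  expect_equal(rev_fd$vprime, -fd$vprime[, , 3:1])
  expect_error(frame_difference(array(1, c(4, 4, 1))), ">= 2 frames")
})

test_that("movement energy sums absolute pixel differences", {
  v <- array(0, c(4, 4, 3))
  v[1, 1, 2] <- 5  # one +5 then -5 step
  D <- frame_energy(frame_difference(v))
  expect_equal(D, c(5, 5))
  expect_equal(frame_energy(frame_difference(array(1, c(3, 3, 4)))),
               rep(0, 3))
})

test_that("a gliding blob yields near-constant movement energy", {
  vid <- simulate_behavior_video(40, 15, c(24, 24),
                                 profile = behavior_profile_control(15),
                                 bout_mean_off_s = 0, seed = 6)
  D <- frame_energy(frame_difference(vid))
  expect_lt(sd(D) / mean(D), 0.25)
})

test_that("the envelope recovers a sinusoid's amplitude", {
  fps <- 30
  t <- seq(0, 60, by = 1 / fps)
  a <- 3
  D <- 10 + a * sin(2 * pi * 2 * t)
  # analytic-signal magnitude of a pure sinusoid is its amplitude
  env <- Mod(psiacx:::analytic_signal(D - mean(D)))
  expect_lt(max(abs(env[100:(length(t) - 100)] - a)), 0.05 * a)
  # after the zero-phase low-pass and mean restoration, M sits near
  # mean + amplitude-envelope smoothed to DC
  tr <- movement_envelope(D, fps)
  expect_lt(max(abs(tr$M[200:(length(t) - 200)] - (10 + a))), 0.2 * a)
  expect_all_equal(movement_envelope(rep(0, 512), fps)$M, rep(0, 512))
  expect_error(movement_envelope(D, fps, lowpass_hz = 20), "Nyquist")
})

test_that("movement maps localize activity and normalize jointly", {
  expect_true(all(spatial_movement_map(
    frame_difference(array(1, c(8, 8, 20))), c(0, 1), fps = 30)$map == 0))
  # movement confined to the upper-left quadrant
  set.seed(8)
  v <- array(0.1, c(16, 16, 240))
  for (k in 1:240) v[1:8, 1:8, k] <- 0.1 + runif(64)
  fd <- frame_difference(v)
  m1 <- spatial_movement_map(fd, c(0, 240 / 30 / 60), fps = 30)
  expect_true(all(m1$map[9:16, ] == 0) && all(m1$map[, 9:16] == 0))
  expect_gt(max(m1$map[1:8, 1:8]), 0)
  m2 <- m1; m2$map <- m1$map / 2
  norm <- normalize_movement_maps(list(m1, m2))
  expect_equal(max(vapply(norm, function(m) max(m$map), numeric(1))), 1)
  expect_true(all(vapply(norm, function(m) m$normalized, logical(1))))
})

test_that("window means average M over the stated minutes", {
  M <- c(rep(1, 600), rep(0, 1500))  # 10 min at 1 fps, then 25 min
  tr <- fake_movement_trace(M, fps = 1)
  wm <- suppressWarnings(window_means(tr, list(c(0, 10), c(10, 60))))
  expect_equal(unname(wm), c(1, 0))
  expect_warning(window_means(tr, list(c(0, 60))), "truncated")
  cm <- window_means(fake_movement_trace(rep(2.5, 1200), 1),
                     list(c(0, 10), c(10, 20)))
  expect_equal(unname(cm), c(2.5, 2.5))
  expect_error(window_means(tr, list(c(40, 50))), "beyond the end")
})

test_that("template correlation matches proportional and inverted traces", {
  counts <- c(5, 3, 2, 1, 0, 0)
  tmpl <- htr_template(rep(1:6 * 60 - 30, counts), duration_s = 360)
  expect_equal(tmpl$counts, counts)
  M <- rep(counts, each = 60) * 2          # proportional, 1 fps
  expect_equal(template_correlation(fake_movement_trace(M, 1), tmpl), 1)
  Minv <- -rep(counts, each = 60) + 10
  expect_equal(template_correlation(fake_movement_trace(Minv, 1), tmpl), -1)
  expect_warning(
    r <- template_correlation(fake_movement_trace(rep(1, 360), 1), tmpl),
    "zero-variance")
  expect_true(is.na(r))
})

test_that("hypoactive videos drop movement after the programmed switch", {
  vid <- simulate_behavior_video(
    600, 15, c(24, 24),
    profile = behavior_profile_hypoactive(300, 20, 3), seed = 13)
  tr <- movement_trace(vid)
  wm <- window_means(tr, list(c(0, 5), c(5, 10)))
  expect_lt(wm[[2]], wm[[1]])
})

test_that("the envelope's time profile tracks the programmed speed", {
  vid <- simulate_behavior_video(
    1200, 15, c(24, 24),
    profile = behavior_profile_hypoactive(600, 20, 3), seed = 8)
  tr <- movement_trace(vid)
  b <- 60 * vid$fps  # one-minute bins average over the bout timescale
  nb <- floor(length(tr$M) / b)
  m_binned <- tapply(tr$M[seq_len(nb * b)], rep(seq_len(nb), each = b),
                     mean)
  s_binned <- tapply(vid$truth_speed[1 + seq_len(nb * b)],
                     rep(seq_len(nb), each = b), mean)
  expect_gt(cor(m_binned, s_binned), 0.9)
})

test_that("the chain ignores constant offsets and scales with contrast", {
  vid <- simulate_behavior_video(60, 15, c(16, 16), seed = 17)
  M0 <- movement_trace(vid)$M
  shifted <- vid; shifted$frames <- vid$frames + 5
  expect_all_equal(movement_trace(shifted)$M, M0, tol = 1e-9)
  scaled <- vid; scaled$frames <- vid$frames * 3
  expect_all_equal(movement_trace(scaled)$M, 3 * M0, tol = 1e-8)
})
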