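# ROI masks, trace extraction, neuropil correction, QC, dF/F and sigma
# normalization.

test_that("distant ROIs are disjoint and neuropil respects the 3 px gap", {
  centers <- rbind(c(20, 20), c(60, 60))
  masks <- build_roi_masks(centers, c(80, 80))
  r1 <- masks$rois[[1]]; r2 <- masks$rois[[2]]
  expect_length(intersect(r1$somatic_pixels, r2$somatic_pixels), 0)
  expect_length(intersect(r1$somatic_pixels, r1$neuropil_pixels), 0)
  # min Euclidean distance from any neuropil pixel to the somatic set >= gap
  to_xy <- function(px) cbind((px - 1) %/% 80 + 1, (px - 1) %% 80 + 1)
  s <- to_xy(r1$somatic_pixels); np <- to_xy(r1$neuropil_pixels)
  dmin <- min(sqrt(outer(np[, 1], s[, 1], "-")^2 +
                     outer(np[, 2], s[, 2], "-")^2))
  expect_gte(dmin, 3)
})

test_that("overlapping somatic pixels are excluded from both neurons", {
  centers <- rbind(c(40, 40), c(44, 40))
  masks <- build_roi_masks(centers, c(80, 80))
  # brute-force oracle: build each annulus independently and intersect
  annulus <- function(cx, cy) {
    xs <- matrix(1:80, 80, 80, byrow = TRUE); ys <- matrix(1:80, 80, 80)
    d <- sqrt((xs - cx)^2 + (ys - cy)^2)
    which(d >= 2 & d <= 6)
  }
  a1 <- annulus(40, 40); a2 <- annulus(44, 40)
  shared <- intersect(a1, a2)
  expect_gt(length(shared), 0)
  expect_setequal(masks$rois[[1]]$somatic_pixels, setdiff(a1, shared))
  expect_setequal(masks$rois[[2]]$somatic_pixels, setdiff(a2, shared))
  # neuropil never overlaps any somatic set
  all_soma <- c(masks$rois[[1]]$somatic_pixels,
                masks$rois[[2]]$somatic_pixels)
  for (r in masks$rois)
    expect_length(intersect(r$neuropil_pixels, all_soma), 0)
})

test_that("border ROIs warn and fully swallowed neurons are dropped", {
  expect_warning(build_roi_masks(rbind(c(5, 5)), c(64, 64)), "truncated")
  expect_warning(
    masks <- build_roi_masks(rbind(c(30, 30), c(30, 30)), c(64, 64)),
    "empty somatic"
  )
  expect_length(masks$rois, 0)
})

test_that("trace extraction averages the painted pixel values exactly", {
  masks <- build_roi_masks(rbind(c(20, 20), c(50, 50)), c(70, 70))
  soma_vals <- rbind(sin(1:40) + 2, cos(1:40) + 2)
  np_vals <- rbind(rep(0.5, 40), rep(0.25, 40))
  movie <- render_roi_movie(masks, soma_vals, np_vals, background = 0.1)
  tr <- extract_traces(movie, masks, 30)
  expect_all_equal(tr$C_raw, soma_vals)
  expect_all_equal(tr$N, np_vals)
  # uniform movie: both traces equal the constant
  uni <- array(3.5, c(70, 70, 5))
  tru <- extract_traces(uni, masks, 30)
  expect_all_equal(tru$C_raw, matrix(3.5, 2, 5))
  expect_all_equal(tru$N, matrix(3.5, 2, 5))
})

test_that("neuropil correction applies the printed formula", {
  expect_equal(neuropil_correct(10, 10), 3)
  x <- runif(50)
  expect_equal(neuropil_correct(x, rep(0, 50)), x)
  expect_error(neuropil_correct(1:3, 1:2), "equal length")
  fx <- tiny_experiment()
  tr <- neuropil_correct(fx$exper$traces)
  expect_all_equal(tr$C, fx$exper$truth$C_true)
})

test_that("QC keeps strictly positive time-mean traces only", {
  tr <- cell_traces(rbind(rep(1, 10), rep(-0.1, 10), rep(0, 10)),
                    matrix(0, 3, 10), 30)
  tr <- neuropil_correct(tr)
  expect_identical(qc_filter_cells(tr), 1L)
  expect_error(qc_filter_cells(cell_traces(matrix(1, 1, 4),
                                           matrix(0, 1, 4), 30)),
               "neuropil_correct")
})

test_that("dF/F is zero for constant traces and (F - F0)/F0 for steps", {
  proto <- make_tone_protocol(2, 2, repeats = 2, isi_choices_s = 6,
                              seed = 1)
  n_frames <- ceiling(proto$duration_s * 30)
  # constant trace
  tr <- cell_traces(matrix(2, 1, n_frames), matrix(0, 1, n_frames), 30)
  tr <- neuropil_correct(tr)
  tens <- compute_dff(tr, proto)
  expect_all_equal(tens$dff, array(0, dim(tens$dff)))
  # step to 1.5 after each onset on baseline 1.0
  f <- rep(1, n_frames)
  t_s <- (seq_len(n_frames) - 1) / 30
  for (on in proto$trials$onset_s) f[t_s > on & t_s <= on + 4] <- 1.5
  tr2 <- neuropil_correct(cell_traces(rbind(f), matrix(0, 1, n_frames), 30))
  tens2 <- compute_dff(tr2, proto)
  post <- tens2$dff[1, , tens2$time_rel_s > 0]
  expect_all_equal(post, matrix(0.5, nrow(post), ncol(post)))
})

test_that("baseline-window dF/F mean is zero for every trial", {
  fx <- tiny_experiment(trial_noise_sd = 0.3, rho = 0.2)
  tr <- neuropil_correct(fx$exper$traces)
  tens <- compute_dff(tr, fx$proto)
  base_mean <- apply(tens$dff[, , tens$time_rel_s < 0, drop = FALSE],
                     c(1, 2), mean)
  expect_lt(max(abs(base_mean)), 1e-12)
})

test_that("nonpositive baselines exclude the trial with a warning", {
  proto <- make_tone_protocol(2, 2, repeats = 2, isi_choices_s = 6,
                              seed = 1)
  n_frames <- ceiling(proto$duration_s * 30)
  f <- rep(1, n_frames)
  t_s <- (seq_len(n_frames) - 1) / 30
  o1 <- proto$trials$onset_s[1]
  f[t_s >= o1 - 2 & t_s < o1] <- -1  # poison first baseline
  tr <- neuropil_correct(cell_traces(rbind(f), matrix(0, 1, n_frames), 30))
  expect_warning(tens <- compute_dff(tr, proto), "nonpositive baseline")
  expect_equal(dim(tens$dff)[2], 1)
  expect_identical(tens$trials_kept, 2L)
})

test_that("the 1-s response amplitude is the windowed mean", {
  fx <- tiny_experiment()
  tr <- neuropil_correct(fx$exper$traces)
  tens <- compute_dff(tr, fx$proto)
  # constructed tensor values
  tens_const <- tens
  tens_const$dff[] <- 1
  expect_all_equal(response_amplitude(tens_const),
                   matrix(1, 4, nrow(fx$proto$trials)))
  ramp <- seq(0, 1, length.out = sum(tens$time_rel_s > 0 &
                                       tens$time_rel_s <= 1))
  tens_ramp <- tens
  tens_ramp$dff[, , tens$time_rel_s > 0 & tens$time_rel_s <= 1] <-
    rep(ramp, each = 4 * dim(tens$dff)[2])
  expect_lt(max(abs(response_amplitude(tens_ramp) - 0.5)), 1 / 30)
  # generator oracle: windowed kernel mean x evoked amplitude / baseline
  kern <- gcamp_kernel(30)
  expected <- fx$exper$truth$amplitudes * mean(kern[1:30])
  expect_all_equal(response_amplitude(tens), expected, tol = 1e-9)
  expect_error(response_amplitude(tens, window_s = 99), "window")
})

test_that("sigma normalization divides by the trial-amplitude sample SD", {
  # two-trial toy: amplitudes {0, 2} -> sigma sqrt(2)
  proto <- make_tone_protocol(2, 2, repeats = 2, isi_choices_s = 6,
                              seed = 1)
  n_frames <- ceiling(proto$duration_s * 30)
  f <- rep(1, n_frames)
  t_s <- (seq_len(n_frames) - 1) / 30
  o2 <- proto$trials$onset_s[2]
  f[t_s > o2 & t_s <= o2 + 3.5] <- 3  # dff 2 on trial 2, 0 on trial 1
  tr <- neuropil_correct(cell_traces(rbind(f), matrix(0, 1, n_frames), 30))
  tens <- sigma_normalize(compute_dff(tr, proto))
  expect_equal(tens$sigma, sqrt(2), tolerance = 1e-9)
  # after normalization every neuron's amplitude SD is 1
  fx <- tiny_experiment(trial_noise_sd = 0.2)
  trn <- neuropil_correct(fx$exper$traces)
  tn <- sigma_normalize(compute_dff(trn, fx$proto))
  expect_all_equal(apply(response_amplitude(tn), 1, sd), rep(1, 4),
                   tol = 1e-9)
  # idempotent
  expect_identical(sigma_normalize(tn), tn)
})

test_that("zero-sigma neurons are excluded from normalized output", {
  proto <- make_tone_protocol(2, 2, repeats = 2, isi_choices_s = 6,
                              seed = 1)
  n_frames <- ceiling(proto$duration_s * 30)
  flat <- matrix(1, 2, n_frames)
  t_s <- (seq_len(n_frames) - 1) / 30
  o2 <- proto$trials$onset_s[2]
  flat[2, t_s > o2 & t_s <= o2 + 3.5] <- 2
  tr <- neuropil_correct(cell_traces(flat, matrix(0, 2, n_frames), 30))
  expect_warning(tn <- sigma_normalize(compute_dff(tr, proto)),
                 "zero response-amplitude SD")
  expect_identical(tn$neurons_kept, 2L)
})

test_that("the pipeline is invariant to global movie rescaling", {
  fx <- tiny_experiment(trial_noise_sd = 0.1)
  run <- function(scale) {
    tr <- fx$exper$traces
    tr$C_raw <- tr$C_raw * scale
    tr$N <- tr$N * scale
    tn <- sigma_normalize(compute_dff(neuropil_correct(tr), fx$proto))
    response_amplitude(tn)
  }
  expect_all_equal(run(1), run(7.3), tol = 1e-9)
})

test_that("movie -> masks -> traces -> correction recovers truth exactly", {
  fx <- tiny_experiment()
  # centers far enough apart that even the neuropil rings are disjoint,
  # so painted pixel values are unambiguous
  masks <- build_roi_masks(rbind(c(24, 24), c(24, 72), c(72, 24),
                                 c(72, 72)), c(96, 96))
  movie <- render_roi_movie(masks, fx$exper$traces$C_raw,
                            fx$exper$traces$N)
  tr <- neuropil_correct(extract_traces(movie, masks, 30))
  expect_all_equal(tr$C, fx$exper$truth$C_true)
})
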