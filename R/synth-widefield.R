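#' Simulate a widefield movie with a tonotopic gradient
#'
#' Generates a registered widefield stack whose pixels respond to tones
#' with Gaussian log-frequency tuning centered on a ground-truth best
#' frequency (BF). The truth map is a monotone banded gradient: pixels are
#' split into contiguous bands along `gradient_axis`, one band per protocol
#' tone in ascending order, so the true BF always lies on the tone grid and
#' is exactly recoverable by the mapping pipeline in the noiseless limit.
#'
#' Optionally a static multiplicative illumination field (linear ramp
#' `illumination_range[1]` to `illumination_range[2]` along the orthogonal
#' axis) is applied to exercise the homomorphic filter.
#'
#' @param protocol A [make_tone_protocol()] schedule.
#' @param shape Frame shape `c(height, width)`.
#' @param gradient_axis `"x"` (BF varies with column) or `"y"`.
#' @param tuning_width_oct Pixel tuning SD in octaves.
#' @param amplitude Peak evoked dF/F at a pixel's own BF.
#' @param baseline Baseline fluorescence (arbitrary units, > 0).
#' @param illumination_range Length-2 multiplicative illumination ramp, or
#'   `NULL` for flat illumination.
#' @param noise_sd Additive per-pixel, per-frame Gaussian noise SD (applied
#'   before illumination).
#' @param frame_rate_hz Acquisition rate (Hz).
#' @param seed Integer seed for the noise, or `NULL`.
#' @return A `synth_widefield`: `stack` (height x width x frames),
#'   `truth_bf` (height x width matrix of grid BFs, kHz), `illumination`
#'   (matrix or `NULL`), plus the generator parameters.
#' @export
simulate_widefield <- function(protocol, shape = c(40, 40),
                               gradient_axis = c("x", "y"),
                               tuning_width_oct = 0.8,
                               amplitude = 0.5, baseline = 1,
                               illumination_range = NULL,
                               noise_sd = 0.05,
                               frame_rate_hz = 5, seed = NULL) {
  gradient_axis <- match.arg(gradient_axis)
  stopifnot_scalar_number(baseline, "baseline", positive = TRUE)
  h <- shape[1]; w <- shape[2]
  freqs <- protocol$frequencies_khz
  nf <- length(freqs)

  band_of <- function(n) freqs[ceiling(seq_len(n) / n * nf)]
  truth_bf <- if (gradient_axis == "x")
    matrix(band_of(w), h, w, byrow = TRUE) else matrix(band_of(h), h, w)

  rate <- frame_rate_hz
  n_frames <- ceiling(protocol$duration_s * rate)
  kern <- gcamp_kernel(rate)
  lk <- length(kern)
  onset_frame <- frame_at(protocol$trials$onset_s, rate)

  # pixels x frames dF (response numerator), built per trial from the
  # pixel tuning weight at the presented tone
  npx <- h * w
  tune_by_freq <- vapply(freqs, function(f)
    tuning_weight(f, as.vector(truth_bf), tuning_width_oct), numeric(npx))
  fidx <- match(protocol$trials$frequency_khz, freqs)
  flat <- matrix(baseline, npx, n_frames)
  for (tr in seq_len(nrow(protocol$trials))) {
    idx <- onset_frame[tr] + seq_len(lk)
    idx <- idx[idx <= n_frames]
    flat[, idx] <- flat[, idx] +
      (amplitude * tune_by_freq[, fidx[tr]]) %o% kern[seq_along(idx)]
  }
  if (noise_sd > 0)
    flat <- flat + with_local_seed(seed,
      matrix(stats::rnorm(npx * n_frames, sd = noise_sd), npx, n_frames))

  illum <- NULL
  if (!is.null(illumination_range)) {
    ramp <- seq(illumination_range[1], illumination_range[2],
                length.out = if (gradient_axis == "x") h else w)
    illum <- if (gradient_axis == "x") matrix(ramp, h, w)
    else matrix(ramp, h, w, byrow = TRUE)
    flat <- flat * as.vector(illum)
  }

  structure(
    list(stack = array(flat, c(h, w, n_frames)), truth_bf = truth_bf,
         illumination = illum, protocol = protocol,
         tuning_width_oct = tuning_width_oct, amplitude = amplitude,
         baseline = baseline, noise_sd = noise_sd,
         frame_rate_hz = frame_rate_hz, seed = seed),
    class = "synth_widefield"
  )
}
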