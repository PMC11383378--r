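# Synthetic two-photon data generator: tone-evoked GCaMP6s-like transients
# with log-frequency Gaussian tuning, condition-dependent gain, shared-latent
# trial noise, and neuropil contamination at a known coefficient.

#' GCaMP6s-like calcium impulse response
#'
#' Peak-normalized double exponential, rise 0.18 s and decay 1.5 s,
#' truncated at 4 s with a raised-cosine taper over the final 0.5 s. The
#' 4 s support guarantees that with the shortest inter-stimulus interval
#' used here (6 s) a trial's transient has fully decayed before the next
#' trial's 2 s baseline window opens, which keeps noiseless recovery tests
#' exact.
#'
#' @param frame_rate_hz Sampling rate of the returned kernel.
#' @param rise_s,decay_s Rise and decay time constants (s).
#' @param support_s Kernel support (s).
#' @param taper_s Raised-cosine taper length at the end of the support (s).
#' @return Numeric vector of kernel samples starting at the first frame
#'   after the impulse.
#' @export
gcamp_kernel <- function(frame_rate_hz = 30, rise_s = 0.18, decay_s = 1.5,
                         support_s = 4, taper_s = 0.5) {
  t <- seq_len(ceiling(support_s * frame_rate_hz)) / frame_rate_hz
  k <- (1 - exp(-t / rise_s)) * exp(-t / decay_s)
  tap <- rep(1, length(t))
  in_tap <- t > support_s - taper_s
  tap[in_tap] <- 0.5 * (1 + cos(pi * (t[in_tap] - (support_s - taper_s)) /
                                  taper_s))
  k <- k * tap
  k / max(k)
}

#' Parameters of the synthetic two-photon generator
#'
#' Houses the ground truth later recovered by the analysis modules. Per-neuron
#' best frequencies are drawn uniformly from the protocol tone grid and base
#' amplitudes log-normally around `base_amplitude` (30% spread) unless given
#' explicitly.
#'
#' @param n_neurons Number of neurons.
#' @param frame_rate_hz Imaging frame rate (Hz).
#' @param bf_khz Optional vector of ground-truth best frequencies (kHz);
#'   `NULL` samples them from the protocol grid at simulation time.
#' @param tuning_width_oct Gaussian tuning SD in octaves.
#' @param base_amplitude Evoked dF/F at the best frequency: either a scalar
#'   log-normal median or a length-`n_neurons` vector.
#' @param condition_gain Named multiplicative response gain per condition,
#'   e.g. `c(Pre = 1, Post1 = 1.4, Post2 = 0.8)`; all entries must be > 0.
#' @param shared_noise_rho Target pairwise noise correlation in `[0, 1)`,
#'   realized through a shared latent trial factor.
#' @param trial_noise_sd Residual SD of the per-trial evoked amplitude.
#' @param neuropil_coeff Contamination coefficient mixing the neuropil trace
#'   into the raw somatic trace (the correction step subtracts 0.7 N(t)).
#' @param baseline_f Baseline fluorescence offset (arbitrary units, > 0) so
#'   dF/F denominators are well defined.
#' @param seed Integer RNG seed for every draw the generator makes.
#' @return A `synth_neural_config` list.
#' @export
synth_neural_config <- function(n_neurons = 100, frame_rate_hz = 30,
                                bf_khz = NULL, tuning_width_oct = 1,
                                base_amplitude = 0.3,
                                condition_gain = c(Pre = 1, Post1 = 1,
                                                   Post2 = 1),
                                shared_noise_rho = 0.1,
                                trial_noise_sd = 0.2,
                                neuropil_coeff = 0.7,
                                baseline_f = 1,
                                seed = 1L) {
  if (n_neurons < 1) stop("`n_neurons` must be >= 1")
  stopifnot_scalar_number(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  if (shared_noise_rho < 0 || shared_noise_rho >= 1)
    stop("`shared_noise_rho` must lie in [0, 1)")
  if (any(condition_gain <= 0)) stop("all condition gains must be > 0")
  if (trial_noise_sd < 0) stop("`trial_noise_sd` must be >= 0")
  stopifnot_scalar_number(baseline_f, "baseline_f", positive = TRUE)
  if (is.null(names(condition_gain)))
    names(condition_gain) <- paste0("cond", seq_along(condition_gain))
  structure(
    list(n_neurons = as.integer(n_neurons), frame_rate_hz = frame_rate_hz,
         bf_khz = bf_khz, tuning_width_oct = tuning_width_oct,
         base_amplitude = base_amplitude, condition_gain = condition_gain,
         shared_noise_rho = shared_noise_rho,
         trial_noise_sd = trial_noise_sd,
         neuropil_coeff = neuropil_coeff, baseline_f = baseline_f,
         seed = as.integer(seed)),
    class = "synth_neural_config"
  )
}

# Gaussian tuning on the octave (log2-frequency) axis.
tuning_weight <- function(freq_khz, bf_khz, width_oct) {
  d <- log2(freq_khz) - log2(bf_khz)
  exp(-d^2 / (2 * width_oct^2))
}

# Draw per-neuron ground truth (BF, base amplitude) from the config seed so
# every condition simulated from the same config sees the same population.
draw_neuron_truth <- function(config, protocol) {
  with_local_seed(config$seed, {
    bf <- config$bf_khz
    if (is.null(bf))
      bf <- sample(protocol$frequencies_khz, config$n_neurons, replace = TRUE)
    if (length(bf) != config$n_neurons)
      stop("`bf_khz` must have one entry per neuron")
    base <- config$base_amplitude
    if (length(base) == 1L)
      base <- stats::rlnorm(config$n_neurons, log(base), 0.3)
    if (length(base) != config$n_neurons)
      stop("`base_amplitude` must be scalar or one entry per neuron")
    list(bf_khz = bf, base_amplitude = base)
  })
}

#' Simulate per-trial evoked response amplitudes
#'
#' The amplitude model at the heart of the generator: neuron `i` on a trial
#' at frequency `f` responds with
#' `gain * base_i * exp(-(log2 f - log2 BF_i)^2 / (2 w^2)) + eps`, where
#' `eps = sd * (sqrt(rho) z_trial + sqrt(1 - rho) eta)` couples neurons
#' through a shared unit-normal trial factor `z` so the expected pairwise
#' noise correlation equals `rho`.
#'
#' @param config A [synth_neural_config()].
#' @param protocol A [make_tone_protocol()] schedule.
#' @param condition Name or index into `config$condition_gain`.
#' @return Matrix (neurons x trials) of evoked amplitudes, with the drawn
#'   ground truth attached as attributes `bf_khz` and `base_amplitude`.
#' @export
simulate_trial_amplitudes <- function(config, protocol, condition = 1L) {
  gain <- config$condition_gain[[condition]]
  truth <- draw_neuron_truth(config, protocol)
  n <- config$n_neurons
  n_trials <- nrow(protocol$trials)
  tune <- outer(truth$bf_khz, protocol$trials$frequency_khz,
                function(bf, f) tuning_weight(f, bf, config$tuning_width_oct))
  signal_amp <- gain * truth$base_amplitude * tune
  cond_idx <- if (is.character(condition))
    match(condition, names(config$condition_gain)) else as.integer(condition)
  if (is.na(cond_idx) || cond_idx < 1 ||
      cond_idx > length(config$condition_gain))
    stop("unknown condition: ", condition)
  noise_seed <- derive_seeds(config$seed,
                             length(config$condition_gain))[cond_idx]
  eps <- with_local_seed(noise_seed, {
    z <- stats::rnorm(n_trials)
    eta <- matrix(stats::rnorm(n * n_trials), n, n_trials)
    config$trial_noise_sd *
      (sqrt(config$shared_noise_rho) * rep(z, each = n) +
         sqrt(1 - config$shared_noise_rho) * eta)
  })
  amp <- signal_amp + eps
  attr(amp, "bf_khz") <- truth$bf_khz
  attr(amp, "base_amplitude") <- truth$base_amplitude
  amp
}

#' Simulate one imaging session
#'
#' Places the trial amplitudes from [simulate_trial_amplitudes()] on the
#' frame timebase by convolving per-trial impulses with the
#' [gcamp_kernel()], adds the baseline offset, and contaminates the somatic
#' trace with `neuropil_coeff` times a slowly varying neuropil trace:
#' `C_raw(t) = C_true(t) + coeff * N(t)`. With the default coefficient 0.7
#' the standard correction recovers the true trace exactly.
#'
#' @inheritParams simulate_trial_amplitudes
#' @return A `synth_experiment`: list with `traces` (a [cell_traces]
#'   container holding `C_raw` and `N`), the `protocol`, the `condition`
#'   label, and `truth` (config, per-neuron BF and base amplitude, the
#'   evoked amplitude matrix, and the uncontaminated traces `C_true`).
#' @export
simulate_experiment <- function(config, protocol, condition = 1L) {
  amp <- simulate_trial_amplitudes(config, protocol, condition)
  rate <- config$frame_rate_hz
  n_frames <- ceiling(protocol$duration_s * rate)
  kern <- gcamp_kernel(rate)
  lk <- length(kern)
  n <- config$n_neurons

  onset_frame <- frame_at(protocol$trials$onset_s, rate)
  C_true <- matrix(config$baseline_f, n, n_frames)
  for (tr in seq_len(nrow(protocol$trials))) {
    idx <- onset_frame[tr] + seq_len(lk)
    idx <- idx[idx <= n_frames]
    C_true[, idx] <- C_true[, idx] + amp[, tr] %o% kern[seq_along(idx)]
  }

  t_s <- (seq_len(n_frames) - 1) / rate
  phase <- with_local_seed(config$seed + 13L, stats::runif(n, 0, 2 * pi))
  N <- 0.5 * config$baseline_f *
    (1 + 0.2 * sin(outer(phase, 2 * pi * 0.05 * t_s, "+")))
  C_raw <- C_true + config$neuropil_coeff * N

  cond_name <- if (is.character(condition)) condition else
    names(config$condition_gain)[condition]
  structure(
    list(
      traces = cell_traces(C_raw, N, rate),
      protocol = protocol,
      condition = cond_name,
      truth = list(config = config,
                   bf_khz = attr(amp, "bf_khz"),
                   base_amplitude = attr(amp, "base_amplitude"),
                   amplitudes = amp[, , drop = FALSE],
                   C_true = C_true)
    ),
    class = "synth_experiment"
  )
}

#' Simulate all conditions of a session series
#'
#' One [simulate_experiment()] per entry of `config$condition_gain`, sharing
#' the neuron population (the paper's Pre / Post 1 / Post 2 design images a
#' different field of view per session; sharing neurons here is what makes
#' gain-recovery tests sharp, and pooled statistics are insensitive to it).
#'
#' @inheritParams simulate_trial_amplitudes
#' @return Named list of `synth_experiment` objects.
#' @export
simulate_conditions <- function(config, protocol) {
  conds <- names(config$condition_gain)
  stats::setNames(lapply(conds, function(cn)
    simulate_experiment(config, protocol, cn)), conds)
}

#' Paint a registered movie from per-ROI traces
#'
#' Renders a synthetic movie in which every somatic pixel of neuron `i`
#' carries `somatic[i, t]` and every neuropil-ring pixel carries
#' `neuropil[i, t]`, on a constant background. Together with
#' [build_roi_masks()] and [extract_traces()] this closes the loop for exact
#' end-to-end recovery tests.
#'
#' @param masks A [build_roi_masks()] result.
#' @param somatic,neuropil Matrices (neurons x frames) of pixel values.
#' @param background Background pixel value.
#' @return Numeric array `height x width x frames`.
#' @export
render_roi_movie <- function(masks, somatic, neuropil,
                             background = 0.05) {
  n_frames <- ncol(somatic)
  npx <- prod(masks$image_shape)
  flat <- matrix(background, npx, n_frames)
  for (i in seq_along(masks$rois)) {
    roi <- masks$rois[[i]]
    flat[roi$somatic_pixels, ] <-
      matrix(somatic[i, ], length(roi$somatic_pixels), n_frames,
             byrow = TRUE)
    flat[roi$neuropil_pixels, ] <-
      matrix(neuropil[i, ], length(roi$neuropil_pixels), n_frames,
             byrow = TRUE)
  }
  array(flat, c(masks$image_shape, n_frames))
}
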