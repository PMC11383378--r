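#' Pairwise noise correlations from trial response amplitudes
#'
#' For each neuron the mean response to every frequency is subtracted from
#' that frequency's trials; the residuals, pooled over all trials, are
#' correlated (Pearson) for every neuron pair. The experiment-level summary
#' is the mean over distinct pairs (upper triangle).
#'
#' Pairs involving a neuron with zero residual variance are undefined; they
#' are set to `NA`, excluded from the experiment mean, and flagged with a
#' warning.
#'
#' @param amplitudes Matrix (neurons x trials) of response amplitudes
#'   (conventionally the sigma-normalized 1-s amplitudes; the estimator is
#'   invariant to per-neuron affine rescaling).
#' @param trial_frequencies Frequency (kHz) of each trial column; >= 2
#'   trials per frequency and >= 2 neurons are required.
#' @return A `noise_corr` object: `pair_matrix` (symmetric, unit diagonal),
#'   `experiment_mean`, `n_neurons`, `n_trials`.
#' @export
noise_correlations <- function(amplitudes, trial_frequencies) {
  amplitudes <- rbind(amplitudes)
  n <- nrow(amplitudes)
  if (n < 2) stop("need >= 2 neurons")
  if (ncol(amplitudes) != length(trial_frequencies))
    stop("one trial frequency per amplitude column is required")
  if (any(table(trial_frequencies) < 2))
    stop("need >= 2 trials per frequency")

  f <- factor(trial_frequencies)
  freq_means <- t(apply(amplitudes, 1, function(a) tapply(a, f, mean)))
  resid <- amplitudes - freq_means[, as.integer(f), drop = FALSE]

  sds <- apply(resid, 1, stats::sd)
  pair <- suppressWarnings(stats::cor(t(resid)))
  diag(pair) <- 1
  if (any(sds == 0)) {
    warning(sum(sds == 0),
            " neuron(s) with zero residual variance: their pairs are NA",
            call. = FALSE)
    pair[sds == 0, ] <- NA_real_
    pair[, sds == 0] <- NA_real_
    diag(pair) <- ifelse(sds == 0, NA_real_, 1)
  }
  structure(
    list(pair_matrix = pair,
         experiment_mean = mean(pair[upper.tri(pair)], na.rm = TRUE),
         n_neurons = n, n_trials = ncol(amplitudes)),
    class = "noise_corr"
  )
}

#' @export
print.noise_corr <- function(x, ...) {
  cat("Noise correlations:", x$n_neurons, "neurons,",
      x$n_trials, "trials; experiment mean =",
      signif(x$experiment_mean, 3), "\n")
  invisible(x)
}
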