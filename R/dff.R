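# Stimulus-aligned dF/F rasters, 1-s response amplitudes and sigma
# normalization.

#' Cut traces into stimulus-aligned dF/F trial rasters
#'
#' For every trial, baseline fluorescence is the mean of the corrected trace
#' over the silent window `[onset - baseline_window_s, onset)`; dF/F is
#' `(F - F_base) / F_base` over the raster `[onset - baseline_window_s,
#' onset + tone_duration + post_window_s]`. Trials whose baseline is not
#' strictly positive for every neuron are excluded with a warning (dF/F is
#' undefined there).
#'
#' Window edges live on the frame grid: the raster holds `round(bw * rate)`
#' baseline frames (relative times in `[-bw, 0)`) followed by
#' `round((tone + post) * rate)` response frames (relative times in
#' `(0, tone + post]`).
#'
#' @param traces A neuropil-corrected [cell_traces] object.
#' @param protocol The [make_tone_protocol()] schedule the movie was
#'   recorded under.
#' @param baseline_window_s Silent baseline window length (s).
#' @param post_window_s Post-tone window length (s); the raster extends to
#'   tone offset plus this.
#' @param neurons Optional neuron subset (e.g. from [qc_filter_cells()]).
#' @return A `trial_tensor`: `dff` array (neurons x trials x time),
#'   `time_rel_s`, `trial_frequencies`, `trials_kept`, the window
#'   parameters, `frame_rate_hz`, and `sigma = NULL` until
#'   [sigma_normalize()] runs.
#' @export
compute_dff <- function(traces, protocol, baseline_window_s = 2,
                        post_window_s = 3, neurons = NULL) {
  if (is.null(traces$C))
    stop("run `neuropil_correct()` before computing dF/F")
  C <- traces$C
  if (!is.null(neurons)) C <- C[neurons, , drop = FALSE]
  rate <- traces$frame_rate_hz
  nb <- round(baseline_window_s * rate)
  np <- round((protocol$tone_duration_s + post_window_s) * rate)
  if (nb < 1) stop("baseline window shorter than one frame")

  onset_frame <- frame_at(protocol$trials$onset_s, rate)
  n_trials <- nrow(protocol$trials)
  n <- nrow(C)
  if (max(onset_frame) + np > ncol(C) || min(onset_frame) - nb < 1)
    stop("protocol windows exceed the trace extent")

  dff <- array(NA_real_, c(n, n_trials, nb + np))
  bad <- logical(n_trials)
  for (tr in seq_len(n_trials)) {
    o <- onset_frame[tr]
    base <- rowMeans(C[, (o - nb):(o - 1), drop = FALSE])
    if (any(base <= 0)) { bad[tr] <- TRUE; next }
    seg <- C[, (o - nb):(o + np), drop = FALSE]
    seg <- seg[, -(nb + 1), drop = FALSE]  # drop the onset frame itself
    dff[, tr, ] <- (seg - base) / base
  }
  if (any(bad)) {
    warning(sum(bad), " trial(s) excluded: nonpositive baseline fluorescence",
            call. = FALSE)
    dff <- dff[, !bad, , drop = FALSE]
  }
  keep <- which(!bad)
  structure(
    list(dff = dff,
         time_rel_s = c(-(nb:1), seq_len(np)) / rate,
         trial_frequencies = protocol$trials$frequency_khz[keep],
         trials_kept = keep,
         baseline_window_s = baseline_window_s,
         post_window_s = post_window_s,
         tone_duration_s = protocol$tone_duration_s,
         frame_rate_hz = rate,
         sigma = NULL, normalized = FALSE),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$dff)
  cat("Trial tensor:", d[1], "neurons x", d[2], "trials x", d[3],
      "frames (", min(x$time_rel_s), "to", max(x$time_rel_s), "s rel. onset)",
      if (x$normalized) "[sigma-normalized]" else "", "\n")
  invisible(x)
}

#' Mean dF/F in the first second after stimulus onset
#'
#' The scalar response used throughout: the mean of dF/F over the half-open
#' window `(onset, onset + window_s]`.
#'
#' @param tensor A [compute_dff()] trial tensor (raw or sigma-normalized).
#' @param window_s Averaging window length (s).
#' @return Matrix (neurons x trials) of response amplitudes.
#' @export
response_amplitude <- function(tensor, window_s = 1) {
  idx <- which(tensor$time_rel_s > 0 &
                 tensor$time_rel_s <= window_s + 1e-9)
  if (length(idx) < round(window_s * tensor$frame_rate_hz))
    stop("response window exceeds the trial raster")
  amp <- apply(tensor$dff[, , idx, drop = FALSE], c(1, 2), mean)
  matrix(amp, dim(tensor$dff)[1], dim(tensor$dff)[2])
}

#' Normalize dF/F by each neuron's response-amplitude SD
#'
#' Divides every dF/F sample of neuron `i` by `sigma_i`, the sample SD
#' (denominator n - 1) over trials of that neuron's 1-s response
#' amplitudes, yielding dF/F(sigma). Neurons with `sigma = 0` cannot be
#' normalized and are excluded with a warning.
#'
#' @param tensor A raw [compute_dff()] trial tensor with >= 2 trials.
#' @param window_s Amplitude window used to define sigma (s).
#' @return The tensor in dF/F(sigma) units, with `sigma` (per retained
#'   neuron) and `neurons_kept` recorded.
#' @export
sigma_normalize <- function(tensor, window_s = 1) {
  if (isTRUE(tensor$normalized)) return(tensor)
  if (dim(tensor$dff)[2] < 2)
    stop("sigma normalization needs >= 2 trials")
  amp <- response_amplitude(tensor, window_s)
  sigma <- apply(amp, 1, stats::sd)
  keep <- which(sigma > 0)
  if (length(keep) < length(sigma))
    warning(length(sigma) - length(keep),
            " neuron(s) excluded: zero response-amplitude SD", call. = FALSE)
  tensor$dff <- tensor$dff[keep, , , drop = FALSE] / sigma[keep]
  tensor$sigma <- sigma[keep]
  tensor$neurons_kept <- keep
  tensor$normalized <- TRUE
  tensor
}
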