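# Frequency tuning curves, best frequency, and off-BF selectivity.

#' Frequency tuning curves and best frequencies
#'
#' Averages each neuron's 1-s response amplitudes within frequency to give
#' its frequency tuning curve (FTC), and assigns the best frequency (BF) as
#' the FTC peak. Exact ties are broken to the lowest frequency.
#'
#' @param amplitudes Matrix (neurons x trials) of response amplitudes, e.g.
#'   from [response_amplitude()] on a sigma-normalized tensor.
#' @param trial_frequencies Frequency (kHz) of every trial column.
#' @param frequencies Optional full protocol tone set; defaults to the
#'   sorted unique trial frequencies. Every frequency must have >= 1 trial.
#' @return A `tuning_curves` object: `frequencies_khz`, `response`
#'   (neurons x frequencies matrix of mean amplitudes), `bf_khz`,
#'   `bf_index`, `n_trials` per frequency.
#' @export
tuning_curve <- function(amplitudes, trial_frequencies,
                         frequencies = NULL) {
  amplitudes <- rbind(amplitudes)
  if (ncol(amplitudes) != length(trial_frequencies))
    stop("one trial frequency per amplitude column is required")
  if (is.null(frequencies))
    frequencies <- sort(unique(trial_frequencies))
  idx <- match(trial_frequencies, frequencies)
  if (anyNA(idx)) stop("trial frequencies outside the protocol set")
  n_trials <- tabulate(idx, nbins = length(frequencies))
  if (any(n_trials == 0))
    stop("every protocol frequency needs at least one trial")
  resp <- t(apply(amplitudes, 1, function(a)
    tapply(a, factor(idx, levels = seq_along(frequencies)), mean)))
  resp <- matrix(resp, nrow(amplitudes), length(frequencies))
  bf_index <- apply(resp, 1, which.max)  # first max = lowest frequency
  structure(
    list(frequencies_khz = frequencies, response = resp,
         bf_khz = frequencies[bf_index], bf_index = bf_index,
         n_trials = n_trials),
    class = "tuning_curves"
  )
}

#' @export
print.tuning_curves <- function(x, ...) {
  cat("Tuning curves:", nrow(x$response), "neurons x",
      length(x$frequencies_khz), "frequencies (",
      fmt_khz(min(x$frequencies_khz)), "-",
      fmt_khz(max(x$frequencies_khz)), "kHz )\n")
  print(table(BF_khz = fmt_khz(x$bf_khz)))
  invisible(x)
}

#' @export
plot.tuning_curves <- function(x, neurons = seq_len(min(nrow(x$response), 8)),
                               ...) {
  graphics::matplot(log2(x$frequencies_khz),
                    t(x$response[neurons, , drop = FALSE]),
                    type = "b", pch = 16, lty = 1,
                    xlab = "frequency (log2 kHz)",
                    ylab = "mean response", ...)
  invisible(x)
}

#' Peak-normalize tuning curves
#'
#' Scales each neuron's FTC so the peak equals 1. Neurons with a
#' nonpositive peak cannot be normalized and are excluded with a warning.
#'
#' @param ftc A [tuning_curve()] result.
#' @return A `tuning_curves` object with unit peaks and `neurons_kept`
#'   recording the retained rows.
#' @export
peak_normalize <- function(ftc) {
  peak <- apply(ftc$response, 1, max)
  keep <- which(peak > 0)
  if (length(keep) < length(peak))
    warning(length(peak) - length(keep),
            " neuron(s) excluded: nonpositive FTC peak", call. = FALSE)
  ftc$response <- ftc$response[keep, , drop = FALSE] / peak[keep]
  ftc$bf_khz <- ftc$bf_khz[keep]
  ftc$bf_index <- ftc$bf_index[keep]
  ftc$neurons_kept <- keep
  ftc
}

#' Average peak-normalized FTCs within best-frequency groups
#'
#' Neurons sharing a BF are averaged pointwise; with the canonical 10-tone
#' protocol this yields up to 10 group curves per condition. Empty BF
#' groups are absent from the output.
#'
#' @param ftc A peak-normalized [tuning_curve()] result.
#' @return Long data frame with columns `bf_khz`, `frequency_khz`, `mean`,
#'   `sem`, `n_neurons`.
#' @export
group_average_ftc <- function(ftc) {
  groups <- split(seq_along(ftc$bf_khz), ftc$bf_khz)
  out <- lapply(names(groups), function(g) {
    rows <- groups[[g]]
    m <- ftc$response[rows, , drop = FALSE]
    data.frame(
      bf_khz = as.numeric(g),
      frequency_khz = ftc$frequencies_khz,
      mean = colMeans(m),
      sem = if (nrow(m) > 1) apply(m, 2, stats::sd) / sqrt(nrow(m)) else 0,
      n_neurons = nrow(m)
    )
  })
  do.call(rbind, out)
}

#' Off-BF response as a percentage of the BF response
#'
#' FTC selectivity: 100 x mean response over the off-BF frequencies divided
#' by the response at BF. Neurons with a nonpositive BF response are
#' excluded (`NA`) with a warning.
#'
#' @param ftc A [tuning_curve()] result (raw or peak-normalized).
#' @return Numeric vector, one percentage per neuron (`NA` where excluded).
#' @export
off_bf_ratio <- function(ftc) {
  n <- nrow(ftc$response)
  out <- rep(NA_real_, n)
  bad <- 0L
  for (i in seq_len(n)) {
    bf_resp <- ftc$response[i, ftc$bf_index[i]]
    if (bf_resp <= 0) { bad <- bad + 1L; next }
    out[i] <- 100 * mean(ftc$response[i, -ftc$bf_index[i]]) / bf_resp
  }
  if (bad > 0)
    warning(bad, " neuron(s) excluded: nonpositive BF response",
            call. = FALSE)
  out
}
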