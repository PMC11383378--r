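#' Construct a randomized pure-tone stimulus protocol
#'
#' Builds the tone set and the seeded trial schedule used throughout the
#' pipeline. Frequencies form a geometric series
#' `f_lo * 2^(k / tones_per_octave)` for `k = 0, 1, ...`, retained while the
#' value does not exceed `f_hi` by more than `endpoint_tol` (so a nominal
#' 2--45 kHz range at 2 tones/octave yields the full 10-tone set ending at
#' 45.25 kHz). Each frequency is presented `repeats` times in a seeded random
#' order; consecutive onsets are separated by the tone duration plus an
#' inter-stimulus interval drawn uniformly from `isi_choices_s`.
#'
#' @param f_lo_khz,f_hi_khz Lower and upper bounds of the tone range (kHz).
#' @param tones_per_octave Tones per octave (>= 1).
#' @param repeats Presentations of each frequency.
#' @param isi_choices_s Candidate inter-stimulus intervals (s), drawn
#'   uniformly per trial.
#' @param tone_duration_s Tone duration (s).
#' @param level_db_spl Nominal presentation level (dB SPL); metadata only.
#' @param endpoint_tol Fractional tolerance admitting the upper endpoint
#'   (default 1%).
#' @param seed Integer seed for the trial order and ISI draws, or `NULL` to
#'   use the current RNG state.
#'
#' @return A `tone_protocol`: list with `frequencies_khz`,
#'   `repeats_per_freq`, `isi_choices_s`, `tone_duration_s`, `level_db_spl`,
#'   a `trials` data frame (`trial`, `freq_index`, `frequency_khz`,
#'   `onset_s`) and the schedule's total `duration_s`.
#' @examples
#' p <- make_tone_protocol(seed = 1)
#' length(p$frequencies_khz)  # 10
#' @export
make_tone_protocol <- function(f_lo_khz = 2, f_hi_khz = 45,
                               tones_per_octave = 2, repeats = 20,
                               isi_choices_s = c(6, 7, 8),
                               tone_duration_s = 0.5,
                               level_db_spl = 70,
                               endpoint_tol = 0.01,
                               seed = NULL) {
  stopifnot_scalar_number(f_lo_khz, "f_lo_khz", positive = TRUE)
  stopifnot_scalar_number(f_hi_khz, "f_hi_khz", positive = TRUE)
  if (f_lo_khz > f_hi_khz) stop("`f_lo_khz` must be <= `f_hi_khz`")
  if (tones_per_octave < 1) stop("`tones_per_octave` must be >= 1")
  if (repeats < 1) stop("`repeats` must be >= 1")
  if (length(isi_choices_s) < 1 || any(isi_choices_s <= 0))
    stop("`isi_choices_s` must be positive intervals")
  stopifnot_scalar_number(tone_duration_s, "tone_duration_s", positive = TRUE)

  k <- 0:ceiling(log2(f_hi_khz / f_lo_khz) * tones_per_octave + 1)
  freqs <- f_lo_khz * 2^(k / tones_per_octave)
  freqs <- freqs[freqs <= f_hi_khz * (1 + endpoint_tol)]
  if (length(freqs) == 0) stop("empty frequency set")

  n_trials <- length(freqs) * repeats
  sched <- with_local_seed(seed, {
    order <- sample(rep(seq_along(freqs), repeats))
    isi <- isi_choices_s[sample.int(length(isi_choices_s), n_trials,
                                    replace = TRUE)]
    list(order = order, isi = isi)
  })
  onsets <- cumsum(tone_duration_s + sched$isi)

  trials <- data.frame(
    trial = seq_len(n_trials),
    freq_index = sched$order,
    frequency_khz = freqs[sched$order],
    onset_s = onsets
  )

  structure(
    list(
      frequencies_khz = freqs,
      repeats_per_freq = as.integer(repeats),
      isi_choices_s = isi_choices_s,
      tone_duration_s = tone_duration_s,
      level_db_spl = level_db_spl,
      trials = trials,
      duration_s = onsets[n_trials] + tone_duration_s + max(isi_choices_s)
    ),
    class = "tone_protocol"
  )
}

#' @export
print.tone_protocol <- function(x, ...) {
  cat("Pure-tone protocol:", length(x$frequencies_khz), "frequencies x",
      x$repeats_per_freq, "repeats =", nrow(x$trials), "trials\n")
  cat("  frequencies (kHz):",
      paste(fmt_khz(x$frequencies_khz), collapse = ", "), "\n")
  cat("  tone", x$tone_duration_s, "s at", x$level_db_spl,
      "dB SPL; ISI in {", paste(x$isi_choices_s, collapse = ", "),
      "} s; total", round(x$duration_s, 1), "s\n")
  invisible(x)
}

#' Write / read a trial schedule as CSV
#'
#' Columns `trial`, `frequency_khz`, `onset_s` (the interchange format for
#' stimulus schedules).
#' @param protocol A `tone_protocol`.
#' @param path Output CSV path.
#' @return `write_schedule_csv()` returns `path` invisibly;
#'   `read_schedule_csv()` returns a data frame with the three columns.
#' @export
write_schedule_csv <- function(protocol, path) {
  utils::write.csv(
    protocol$trials[c("trial", "frequency_khz", "onset_s")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial", "frequency_khz", "onset_s")
  if (!all(need %in% names(df)))
    stop("schedule CSV must have columns: ", paste(need, collapse = ", "))
  df[need]
}
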