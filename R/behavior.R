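# Video-based movement quantification: frame differencing, the
# Hilbert-envelope movement trace M, spatial movement maps, windowed means,
# and head-twitch template correlation.

#' Sequential frame differences, V'(f) = V(f + 1) - V(f)
#'
#' @param video A `behavior_video` or an array `height x width x frames`
#'   with at least two frames.
#' @return A `frame_diff`: signed difference array (height x width x
#'   (frames - 1)) and the frame rate.
#' @export
frame_difference <- function(video) {
  fps <- NA_real_
  if (inherits(video, "behavior_video")) {
    fps <- video$fps
    video <- video$frames
  }
  d <- dim(video)
  if (length(d) != 3 || d[3] < 2)
    stop("`video` must be an array with >= 2 frames")
  vp <- video[, , -1, drop = FALSE] - video[, , -d[3], drop = FALSE]
  structure(list(vprime = vp, fps = fps), class = "frame_diff")
}

#' Per-frame movement energy, D(f) = sum of |V'(f)| over pixels
#'
#' Absolute differences are summed: signed differences of a moving object
#' of conserved brightness cancel to near zero, which would defeat the
#' trace's purpose.
#'
#' @param vprime A [frame_difference()] result (or a raw difference array).
#' @return Numeric vector `D`, one value per difference frame.
#' @export
frame_energy <- function(vprime) {
  if (inherits(vprime, "frame_diff")) vprime <- vprime$vprime
  d <- dim(vprime)
  vprime <- abs(vprime)
  dim(vprime) <- c(d[1] * d[2], d[3])
  colSums(vprime)
}

# Analytic signal via the frequency-domain construction: zero the negative
# frequencies, double the positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Movement envelope M from the frame-difference energy
#'
#' The envelope is the magnitude of the analytic signal of mean-removed
#' `D`, smoothed with a zero-phase low-pass filter (Butterworth order 2,
#' cutoff `lowpass_hz`, run forwards and backwards), with the removed mean
#' restored and the result clamped at zero.
#'
#' @param D Energy trace from [frame_energy()].
#' @param fps Frame rate of `D` (Hz).
#' @param lowpass_hz Low-pass cutoff (Hz); must be below the Nyquist rate.
#' @return A `movement_trace`: `M`, `D`, `fps`, `t_s` (time of each
#'   difference frame), `duration_s`.
#' @export
movement_envelope <- function(D, fps, lowpass_hz = 0.5) {
  stopifnot_scalar_number(fps, "fps", positive = TRUE)
  if (lowpass_hz >= fps / 2)
    stop("`lowpass_hz` must be below the Nyquist frequency")
  m <- mean(D)
  env <- Mod(analytic_signal(D - m))
  bf <- signal::butter(2, lowpass_hz / (fps / 2), type = "low")
  M <- pmax(as.numeric(signal::filtfilt(bf, env)) + m, 0)
  structure(
    list(M = M, D = D, fps = fps, t_s = seq_along(D) / fps,
         duration_s = length(D) / fps),
    class = "movement_trace"
  )
}

#' @export
print.movement_trace <- function(x, ...) {
  cat("Movement trace:", length(x$M), "frames @", x$fps, "fps (",
      round(x$duration_s / 60, 1), "min ); mean M =",
      signif(mean(x$M), 3), "\n")
  invisible(x)
}

#' @export
plot.movement_trace <- function(x, ...) {
  graphics::plot(x$t_s / 60, x$M, type = "l", xlab = "time (min)",
                 ylab = "movement M", ...)
  invisible(x)
}

#' Quantify movement from a video in one call
#'
#' [frame_difference()] -> [frame_energy()] -> [movement_envelope()].
#'
#' @param video A `behavior_video` or array.
#' @param fps Frame rate; taken from the video object when available.
#' @param lowpass_hz Envelope low-pass cutoff (Hz).
#' @return A `movement_trace`.
#' @export
movement_trace <- function(video, fps = NULL, lowpass_hz = 0.5) {
  fd <- frame_difference(video)
  if (is.null(fps)) fps <- fd$fps
  if (is.na(fps)) stop("`fps` must be supplied for a raw array")
  movement_envelope(frame_energy(fd), fps, lowpass_hz)
}

#' Spatial movement map over a time window
#'
#' Per-pixel mean of `|V'|` within the window. To denoise, each pixel whose
#' windowed mean falls below twice the standard error of that pixel's
#' `|V'|` values across the full video is set exactly to zero. Maps meant
#' to be compared should be normalized jointly with
#' [normalize_movement_maps()].
#'
#' @param vprime A [frame_difference()] result.
#' @param window_min Length-2 window `c(start, end)` in minutes.
#' @param fps Frame rate; taken from `vprime` when available.
#' @return A `spatial_movement_map`: `map` (height x width), `window_min`,
#'   `normalized = FALSE`.
#' @export
spatial_movement_map <- function(vprime, window_min, fps = NULL) {
  if (inherits(vprime, "frame_diff")) {
    if (is.null(fps)) fps <- vprime$fps
    vprime <- vprime$vprime
  }
  if (is.null(fps) || is.na(fps)) stop("`fps` is required")
  d <- dim(vprime)
  absv <- matrix(abs(vprime), d[1] * d[2], d[3])
  t_s <- seq_len(d[3]) / fps
  idx <- which(t_s > window_min[1] * 60 & t_s <= window_min[2] * 60)
  if (length(idx) == 0) stop("empty time window")
  map <- rowMeans(absv[, idx, drop = FALSE])
  sem <- apply(absv, 1, stats::sd) / sqrt(d[3])
  map[map < 2 * sem] <- 0
  structure(
    list(map = matrix(map, d[1], d[2]), window_min = window_min,
         normalized = FALSE),
    class = "spatial_movement_map"
  )
}

#' Jointly normalize spatial movement maps to their common peak
#'
#' Divides every map by the maximum value across the whole set, so the
#' global peak equals 1 and maps are comparable.
#'
#' @param maps List of [spatial_movement_map()] results.
#' @return The list, normalized, with the shared `normalization` constant
#'   attached to each map.
#' @export
normalize_movement_maps <- function(maps) {
  peak <- max(vapply(maps, function(m) max(m$map), numeric(1)))
  if (peak <= 0) stop("all maps are zero; nothing to normalize")
  lapply(maps, function(m) {
    m$map <- m$map / peak
    m$normalized <- TRUE
    m$normalization <- peak
    m
  })
}

#' Mean movement within time windows
#'
#' @param trace A [movement_envelope()] result.
#' @param windows_min List of `c(start, end)` windows in minutes (default
#'   the 0--10 and 10--60 min windows). Windows extending past the trace
#'   are truncated with a warning (sessions are 40--60 min).
#' @return Named numeric vector of window means of `M`.
#' @export
window_means <- function(trace,
                         windows_min = list(c(0, 10), c(10, 60))) {
  vapply(windows_min, function(wm) {
    t0 <- wm[1] * 60; t1 <- wm[2] * 60
    if (t0 >= trace$duration_s)
      stop("window starts beyond the end of the trace")
    if (t1 > trace$duration_s + 1 / trace$fps) {
      warning("window ", wm[1], "-", wm[2],
              " min truncated to the trace length", call. = FALSE)
      t1 <- trace$duration_s
    }
    mean(trace$M[trace$t_s > t0 & trace$t_s <= t1])
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(vapply(windows_min, function(wm)
      paste0(wm[1], "-", wm[2], "min"), character(1)))
}

#' Bin head-twitch event times into a rate template
#'
#' @param times_s Event times (s).
#' @param duration_s Template extent (s).
#' @param bin_s Bin width (s), default 60.
#' @param condition Optional condition label.
#' @return An `htr_template`: `counts`, `bin_centers_s`, `bin_s`,
#'   `condition`.
#' @export
htr_template <- function(times_s, duration_s, bin_s = 60,
                         condition = NA_character_) {
  breaks <- seq(0, ceiling(duration_s / bin_s) * bin_s, by = bin_s)
  counts <- graphics::hist(times_s[times_s >= 0 & times_s <= duration_s],
                           breaks = breaks, plot = FALSE)$counts
  structure(
    list(counts = counts, bin_centers_s = breaks[-1] - bin_s / 2,
         bin_s = bin_s, condition = condition),
    class = "htr_template"
  )
}

#' Correlate a movement trace against a head-twitch template
#'
#' The movement envelope is binned to the template's bins (mean of `M` per
#' bin; only bins fully covered by the trace are used) and the Pearson
#' correlation with the event counts is returned. A zero-variance input
#' makes the correlation undefined (`NA`, with a warning).
#'
#' @param trace A [movement_envelope()] result.
#' @param template An [htr_template()].
#' @return Correlation coefficient (scalar, possibly `NA`).
#' @export
template_correlation <- function(trace, template) {
  edges <- c(template$bin_centers_s - template$bin_s / 2,
             max(template$bin_centers_s) + template$bin_s / 2)
  n_full <- sum(edges[-1] <= trace$duration_s + 1e-9)
  if (n_full < 2) stop("trace and template share too little time support")
  bin_idx <- findInterval(trace$t_s, edges, left.open = TRUE,
                          rightmost.closed = TRUE)
  keep <- bin_idx >= 1 & bin_idx <= n_full
  m_binned <- tapply(trace$M[keep], factor(bin_idx[keep], 1:n_full), mean)
  counts <- template$counts[seq_len(n_full)]
  if (stats::sd(m_binned) == 0 || stats::sd(counts) == 0) {
    warning("zero-variance input: template correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(m_binned, counts)
}
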