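# Widefield tonotopy: homomorphic illumination filtering, pixel-wise dF/F,
# the dF/F90 frequency-selection criterion, and median-frequency maps.

# Separable Gaussian blur with replicate (edge-extend) padding, written
# in-package because the pipeline routinely blurs with a sigma comparable
# to or larger than the frame itself (the homomorphic filter's default is
# 50 px), where kernel-size limits of general image packages bite.
# The 1-D blur along an axis of length L is a dense L x L weight matrix
# with the out-of-image kernel tails folded onto the edge samples, so a
# constant image stays exactly constant and whole stacks reduce to two
# matrix multiplies per frame.
blur_weights <- function(L, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  W <- matrix(0, L, L)
  idx <- seq_len(L)
  for (o in -r:r) {
    target <- pmin(pmax(idx + o, 1L), L)
    W[cbind(idx, target)] <- W[cbind(idx, target)] + kern[o + r + 1]
  }
  W
}

gauss_blur2d <- function(m, sigma, Wy = NULL, Wx = NULL) {
  if (is.null(Wy)) Wy <- blur_weights(nrow(m), sigma)
  if (is.null(Wx)) Wx <- blur_weights(ncol(m), sigma)
  Wy %*% m %*% t(Wx)
}

#' Homomorphic illumination filter
#'
#' Removes smooth multiplicative background illumination while preserving
#' local image structure: each frame is log-transformed, a large-kernel
#' Gaussian blur of the log image (`sigma = blur_sigma_px`) is subtracted,
#' and the result is exponentiated. Pixel values must be strictly positive;
#' if any are not, a constant offset is added first (with a message).
#'
#' @param frame_stack Array `height x width x frames`.
#' @param blur_sigma_px Gaussian sigma (px) of the background estimate.
#' @return Filtered stack of the same shape.
#' @export
homomorphic_filter <- function(frame_stack, blur_sigma_px = 50) {
  d <- dim(frame_stack)
  if (length(d) != 3) stop("`frame_stack` must be height x width x frames")
  mn <- min(frame_stack)
  if (mn <= 0) {
    offset <- -mn + 1e-3 * max(abs(frame_stack), 1e-3)
    message("homomorphic_filter: adding offset ", signif(offset, 3),
            " to make pixel values positive")
    frame_stack <- frame_stack + offset
    if (min(frame_stack) <= 0) stop("nonpositive pixels after offset")
  }
  Wy <- blur_weights(d[1], blur_sigma_px)
  Wx <- blur_weights(d[2], blur_sigma_px)
  out <- frame_stack
  for (fidx in seq_len(d[3])) {
    l <- log(frame_stack[, , fidx])
    out[, , fidx] <- exp(l - gauss_blur2d(l, blur_sigma_px, Wy, Wx))
  }
  out
}

#' Pixel-wise dF/F traces averaged within tone frequency
#'
#' Applies the same dF/F construction as the two-photon module to every
#' pixel and averages the resulting trial rasters over the repeats of each
#' frequency. Pixels with a nonpositive baseline on a trial are undefined
#' (`NA`) for that trial and drop out of the average.
#'
#' @param frame_stack Array `height x width x frames` (typically the
#'   [homomorphic_filter()] output).
#' @param protocol The tone schedule the movie was recorded under.
#' @param baseline_window_s,post_window_s dF/F windows (s), as in
#'   [compute_dff()].
#' @param frame_rate_hz Acquisition rate (Hz); widefield movies are 5 Hz.
#' @return A `pixel_dff` object: `traces` array (pixels x frequencies x
#'   time), `time_rel_s`, `frequencies_khz`, `image_shape`.
#' @export
pixel_dff <- function(frame_stack, protocol, baseline_window_s = 2,
                      post_window_s = 3, frame_rate_hz = 5) {
  d <- dim(frame_stack)
  if (length(d) != 3) stop("`frame_stack` must be height x width x frames")
  npx <- d[1] * d[2]
  flat <- matrix(frame_stack, npx, d[3])
  rate <- frame_rate_hz
  nb <- round(baseline_window_s * rate)
  np <- round((protocol$tone_duration_s + post_window_s) * rate)
  if (nb < 1) stop("baseline window shorter than one frame")
  onset_frame <- frame_at(protocol$trials$onset_s, rate)
  if (max(onset_frame) + np > d[3] || min(onset_frame) - nb < 1)
    stop("protocol windows exceed the movie extent")

  freqs <- protocol$frequencies_khz
  fidx <- match(protocol$trials$frequency_khz, freqs)
  nt <- nb + np
  sums <- array(0, c(npx, length(freqs), nt))
  counts <- matrix(0, npx, length(freqs))
  n_undef <- 0L
  for (tr in seq_len(nrow(protocol$trials))) {
    o <- onset_frame[tr]
    base <- rowMeans(flat[, (o - nb):(o - 1), drop = FALSE])
    ok <- base > 0
    n_undef <- n_undef + sum(!ok)
    seg <- flat[, c((o - nb):(o - 1), (o + 1):(o + np)), drop = FALSE]
    dff <- (seg - base) / base
    dff[!ok, ] <- 0
    k <- fidx[tr]
    sums[, k, ] <- sums[, k, ] + dff
    counts[, k] <- counts[, k] + ok
  }
  if (n_undef > 0)
    warning(n_undef, " pixel-trial(s) undefined: nonpositive baseline",
            call. = FALSE)
  avg <- sums / as.vector(counts)  # counts recycles over the time axis
  avg[!is.finite(avg)] <- NA_real_
  structure(
    list(traces = avg, time_rel_s = c(-(nb:1), seq_len(np)) / rate,
         frequencies_khz = freqs, image_shape = d[1:2]),
    class = "pixel_dff"
  )
}

#' dF/F90 frequency selection
#'
#' Per pixel: take each frequency-averaged trace's temporal peak, find the
#' maximum `m` over frequencies, and keep the frequencies whose peak is at
#' least `threshold * m` (default within 90% of the per-pixel maximum).
#' Pixels whose peaks are all nonpositive select nothing and stay
#' undefined downstream.
#'
#' @param pdff A [pixel_dff()] result.
#' @param threshold Fraction of the per-pixel maximum peak (default 0.9).
#' @return A `dff90_selection`: logical matrix `selected` (pixels x
#'   frequencies), the per-pixel `peaks` matrix, `frequencies_khz` and
#'   `image_shape`.
#' @export
dff90_select <- function(pdff, threshold = 0.9) {
  peaks <- apply(pdff$traces, c(1, 2), max)
  m <- apply(peaks, 1, max)
  selected <- peaks >= threshold * m & m > 0
  selected[is.na(selected)] <- FALSE
  selected[!is.finite(m) | m <= 0, ] <- FALSE
  structure(
    list(selected = selected, peaks = peaks,
         frequencies_khz = pdff$frequencies_khz,
         image_shape = pdff$image_shape, threshold = threshold),
    class = "dff90_selection"
  )
}

#' Median-frequency tonotopic map
#'
#' Assigns each pixel the median of its dF/F90-selected frequencies,
#' computed on the octave (log2) axis; sets of even cardinality take the
#' geometric mean of the two middle frequencies (equivalently, the midpoint
#' on the octave axis). Pixels with an empty selection are `NA`.
#'
#' @param selection A [dff90_select()] result.
#' @return A `tonotopic_map`: `bf_map` and `response_map` matrices
#'   (height x width; the response map is the per-pixel maximum peak dF/F),
#'   plus the selection itself.
#' @export
tonotopic_map <- function(selection) {
  lf <- log2(selection$frequencies_khz)
  assign_one <- function(sel) {
    if (!any(sel)) return(NA_real_)
    v <- sort(lf[sel])
    k <- length(v)
    mid <- if (k %% 2 == 1) v[(k + 1) / 2] else mean(v[k / 2 + 0:1])
    2^mid
  }
  bf <- apply(selection$selected, 1, assign_one)
  resp <- apply(selection$peaks, 1, max)
  resp[!is.finite(resp)] <- NA_real_
  structure(
    list(bf_map = matrix(bf, selection$image_shape[1],
                         selection$image_shape[2]),
         response_map = matrix(resp, selection$image_shape[1],
                               selection$image_shape[2]),
         selection = selection),
    class = "tonotopic_map"
  )
}

#' @export
print.tonotopic_map <- function(x, ...) {
  ok <- sum(!is.na(x$bf_map))
  cat("Tonotopic map:", paste(dim(x$bf_map), collapse = " x "),
      "px;", ok, "assigned (",
      round(100 * ok / length(x$bf_map)), "% )\n")
  invisible(x)
}

#' Full widefield tonotopy pipeline
#'
#' Convenience chain: [homomorphic_filter()] -> [pixel_dff()] ->
#' [dff90_select()] -> [tonotopic_map()].
#'
#' @inheritParams pixel_dff
#' @inheritParams homomorphic_filter
#' @inheritParams dff90_select
#' @return A [tonotopic_map()].
#' @export
map_tonotopy <- function(frame_stack, protocol, frame_rate_hz = 5,
                         blur_sigma_px = 50, threshold = 0.9,
                         baseline_window_s = 2, post_window_s = 3) {
  filtered <- homomorphic_filter(frame_stack, blur_sigma_px)
  pdff <- pixel_dff(filtered, protocol, baseline_window_s, post_window_s,
                    frame_rate_hz)
  tonotopic_map(dff90_select(pdff, threshold))
}
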