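#' Container for somatic and neuropil fluorescence traces
#'
#' Holds the raw somatic trace `C_raw`, the neuropil trace `N`, and (after
#' [neuropil_correct()]) the corrected trace `C`, all neurons x frames on a
#' shared timebase.
#'
#' @param C_raw,N Matrices (neurons x frames).
#' @param frame_rate_hz Imaging rate (Hz).
#' @param C Optional corrected trace matrix.
#' @return A `cell_traces` object.
#' @export
cell_traces <- function(C_raw, N, frame_rate_hz, C = NULL) {
  C_raw <- rbind(C_raw); N <- rbind(N)
  if (!all(dim(C_raw) == dim(N)))
    stop("`C_raw` and `N` must have identical dimensions")
  stopifnot_scalar_number(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  structure(list(C_raw = C_raw, N = N, C = C,
                 frame_rate_hz = frame_rate_hz,
                 time_s = (seq_len(ncol(C_raw)) - 1) / frame_rate_hz),
            class = "cell_traces")
}

#' @export
print.cell_traces <- function(x, ...) {
  cat("Cell traces:", nrow(x$C_raw), "neurons x", ncol(x$C_raw),
      "frames @", x$frame_rate_hz, "Hz;",
      if (is.null(x$C)) "not yet" else "", "neuropil-corrected\n")
  invisible(x)
}

#' Average ROI pixels into fluorescence traces
#'
#' Somatic and neuropil traces are the per-frame means over each neuron's
#' respective pixel set.
#'
#' @param movie Registered movie, array `height x width x frames`.
#' @param masks An [build_roi_masks()] result matching the movie shape.
#' @param frame_rate_hz Imaging rate (Hz).
#' @return A [cell_traces] object (neurons in mask order).
#' @export
extract_traces <- function(movie, masks, frame_rate_hz = 30) {
  d <- dim(movie)
  if (length(d) != 3 || !all(d[1:2] == masks$image_shape))
    stop("movie dimensions do not match the masks' image shape")
  flat <- matrix(movie, d[1] * d[2], d[3])
  one <- function(px) {
    if (length(px) == 0) stop("empty pixel set")
    colMeans(flat[px, , drop = FALSE])
  }
  C_raw <- t(vapply(masks$rois, function(r) one(r$somatic_pixels),
                    numeric(d[3])))
  N <- t(vapply(masks$rois, function(r) one(r$neuropil_pixels),
                numeric(d[3])))
  cell_traces(C_raw, N, frame_rate_hz)
}

#' Neuropil correction, C(t) = C_raw(t) - coeff * N(t)
#'
#' @param x A [cell_traces] object, or a numeric vector/matrix of raw
#'   somatic fluorescence.
#' @param N Neuropil trace(s), required when `x` is not a `cell_traces`.
#' @param coeff Contamination coefficient (default 0.7).
#' @return Same shape as the input: a `cell_traces` with `C` filled in, or
#'   the corrected vector/matrix.
#' @export
neuropil_correct <- function(x, N = NULL, coeff = 0.7) {
  UseMethod("neuropil_correct")
}

#' @export
neuropil_correct.cell_traces <- function(x, N = NULL, coeff = 0.7) {
  x$C <- x$C_raw - coeff * x$N
  x
}

#' @export
neuropil_correct.default <- function(x, N = NULL, coeff = 0.7) {
  if (is.null(N)) stop("`N` is required")
  if (length(x) != length(N))
    stop("`x` and `N` must have equal length")
  x - coeff * N
}

#' Quality filter: keep neurons with positive time-averaged corrected trace
#'
#' Negative time-mean corrected fluorescence indicates neuropil
#' over-subtraction; such neurons (and exact zeros) are excluded.
#'
#' @param traces A neuropil-corrected [cell_traces] object.
#' @return Integer vector of retained neuron indices.
#' @export
qc_filter_cells <- function(traces) {
  if (is.null(traces$C))
    stop("run `neuropil_correct()` before QC filtering")
  which(rowMeans(traces$C) > 0)
}
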