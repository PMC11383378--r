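#' Build somatic-ring and neuropil-ring pixel masks
#'
#' For each supplied cell center, the somatic ROI is the annulus of pixels
#' whose center-distance `d` satisfies `inner <= d <= outer`
#' (`somatic_radii`), and the neuropil ROI is the ring beginning
#' `neuropil_gap_px` beyond the somatic ROI with width `neuropil_width_px`.
#' Overlap exclusion follows the usual rules for neighboring neurons:
#' pixels claimed by more than one somatic ROI are removed from every
#' somatic set, and any neuropil pixel that falls inside any somatic set is
#' removed from the neuropil set.
#'
#' Centers close enough to the image border that the neuropil ring is
#' clipped keep the truncated ring with a warning; a neuron whose somatic
#' set ends up empty is dropped with a warning.
#'
#' @param centers Two-column matrix or data frame of cell centers
#'   (`x`, `y`), in pixels, 1-indexed.
#' @param image_shape Integer `c(height, width)` of the movie frames.
#' @param somatic_radii Numeric `c(inner, outer)` radii (px) of the somatic
#'   annulus.
#' @param neuropil_gap_px Gap (px) between the somatic ROI and the start of
#'   the neuropil ring.
#' @param neuropil_width_px Width (px) of the neuropil ring.
#' @return An `roi_masks` object: `rois` (per kept neuron: `center`,
#'   `somatic_pixels`, `neuropil_pixels` as linear indices into a frame),
#'   `image_shape`, `kept` (indices into the input centers), and the radii
#'   actually used.
#' @export
build_roi_masks <- function(centers, image_shape,
                            somatic_radii = c(2, 6),
                            neuropil_gap_px = 3,
                            neuropil_width_px = 10) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 2) stop("`centers` must have columns x, y")
  if (any(somatic_radii <= 0) || diff(somatic_radii) < 0)
    stop("`somatic_radii` must be positive and increasing")
  if (neuropil_gap_px < 0 || neuropil_width_px <= 0)
    stop("neuropil gap must be >= 0 and width > 0")
  h <- image_shape[1]; w <- image_shape[2]
  if (any(centers[, 1] < 1 | centers[, 1] > w |
          centers[, 2] < 1 | centers[, 2] > h))
    stop("all centers must lie inside the image")

  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  n <- nrow(centers)
  np_in <- somatic_radii[2] + neuropil_gap_px
  np_out <- np_in + neuropil_width_px

  soma <- vector("list", n)
  neurop <- vector("list", n)
  for (i in seq_len(n)) {
    d <- sqrt((xs - centers[i, 1])^2 + (ys - centers[i, 2])^2)
    soma[[i]] <- which(d >= somatic_radii[1] & d <= somatic_radii[2])
    neurop[[i]] <- which(d >= np_in & d <= np_out)
    full_ring <- centers[i, 1] - np_out >= 1 && centers[i, 1] + np_out <= w &&
      centers[i, 2] - np_out >= 1 && centers[i, 2] + np_out <= h
    if (!full_ring)
      warning("neuron ", i, ": neuropil ring truncated at image border",
              call. = FALSE)
  }

  # Somatic pixels claimed by >1 neuron are excluded from all somatic sets.
  counts <- tabulate(unlist(soma), nbins = h * w)
  shared <- which(counts > 1)
  if (length(shared))
    soma <- lapply(soma, setdiff, shared)
  all_soma <- unlist(soma)
  neurop <- lapply(neurop, setdiff, all_soma)

  kept <- which(lengths(soma) > 0)
  if (length(kept) < n)
    warning("dropping ", n - length(kept),
            " neuron(s) with empty somatic set after overlap exclusion",
            call. = FALSE)
  rois <- lapply(kept, function(i)
    list(center = centers[i, ], somatic_pixels = soma[[i]],
         neuropil_pixels = neurop[[i]]))
  structure(
    list(rois = rois, image_shape = as.integer(c(h, w)), kept = kept,
         somatic_radii = somatic_radii, neuropil_gap_px = neuropil_gap_px,
         neuropil_width_px = neuropil_width_px),
    class = "roi_masks"
  )
}

#' @export
print.roi_masks <- function(x, ...) {
  cat("ROI masks:", length(x$rois), "neurons on a",
      paste(x$image_shape, collapse = " x "), "frame\n")
  cat("  somatic annulus", x$somatic_radii[1], "-", x$somatic_radii[2],
      "px; neuropil ring +", x$neuropil_gap_px, "px gap, width",
      x$neuropil_width_px, "px\n")
  invisible(x)
}

#' Write / read ROI centers as CSV (columns `x`, `y`)
#' @param centers Two-column matrix or data frame of centers.
#' @param path CSV path.
#' @export
write_roi_centers_csv <- function(centers, path) {
  centers <- as.data.frame(as.matrix(centers))
  names(centers) <- c("x", "y")
  utils::write.csv(centers, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_centers_csv
#' @export
read_roi_centers_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("ROI centers CSV must have columns x, y")
  as.matrix(df[c("x", "y")])
}
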