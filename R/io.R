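# Reading and writing movies, maps and result manifests.

#' Write / read an image stack as multi-page TIFF
#'
#' Pages are stored as 32-bit samples. Because the TIFF writer expects data
#' in `[0, 1]`, values are affinely rescaled on write and the original
#' range is recorded in a JSON sidecar (`<path>.range.json`); the reader
#' inverts the rescaling, so round trips are exact up to 32-bit float
#' precision. Constant stacks are stored as-is with a degenerate range.
#'
#' @param stack Numeric array `height x width x frames` (a matrix is
#'   treated as a single page).
#' @param path Output TIFF path.
#' @return `write_stack_tiff()` returns `path` invisibly;
#'   `read_stack_tiff()` returns the array.
#' @export
write_stack_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  rng <- range(stack, finite = TRUE)
  scaled <- if (diff(rng) > 0) (stack - rng[1]) / diff(rng)
  else stack * 0
  pages <- lapply(seq_len(dim(stack)[3]), function(k) scaled[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  jsonlite::write_json(list(min = rng[1], max = rng[2]),
                       paste0(path, ".range.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(unlist(pages),
                 c(dim(pages[[1]])[1:2], length(pages)))
  sidecar <- paste0(path, ".range.json")
  if (file.exists(sidecar)) {
    rng <- jsonlite::read_json(sidecar)
    stack <- stack * (rng$max - rng$min) + rng$min
  }
  stack
}

#' Write an analysis manifest as JSON
#'
#' Records the parameters and per-stage decisions of a pipeline run
#' (windows, sigma values, QC outcomes, seeds) in machine-readable form.
#'
#' @param manifest Named list.
#' @param path Output JSON path.
#' @export
write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
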