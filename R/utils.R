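# Internal helpers shared across modules.

#' Evaluate an expression under a local, seeded RNG scope
#'
#' If `seed` is `NULL` the expression runs under the current RNG state;
#' otherwise [withr::with_seed()] isolates it so callers' RNG streams are
#' untouched.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Derive a vector of child seeds from one top-level seed
#'
#' Used to fan a single study seed out to independent stochastic stages.
#' Child seeds are drawn uniformly below 2^31 so they remain valid R
#' integer seeds.
#' @noRd
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a single finite number", call. = FALSE)
  if (positive && x <= 0)
    stop("`", name, "` must be > 0", call. = FALSE)
  invisible(x)
}

#' Frame index of the last frame at or before time `t`
#'
#' Frames are 1-indexed; frame `f` samples time `(f - 1) / rate`. Windows on
#' the frame grid are half-open `(t0, t1]` with endpoints rounded to the
#' nearest frame.
#' @noRd
frame_at <- function(t, rate) as.integer(round(t * rate)) + 1L

fmt_khz <- function(x) trimws(formatC(x, digits = 4, format = "fg"))
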