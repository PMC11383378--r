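#' Pooled bootstrap test for a difference of means
#'
#' Tests two samples against the null hypothesis of a common distribution.
#' The observed statistic is the absolute difference of means,
#' `delta_mu = |mean(A) - mean(B)|`. The null distribution is the pool of
#' all individual values of `A` and `B` (multiplicities kept); each of the
#' `n_boot` replicates draws two sets `A*` and `B*`, each of size
#' `min(n, m)`, independently with replacement from the pool and computes
#' `delta_mu* = |mean(A*) - mean(B*)|`. The p-value is the fraction of
#' replicates with `delta_mu*` strictly greater than `delta_mu`.
#'
#' `smoothed = TRUE` switches to the add-one estimate
#' `(k + 1) / (n_boot + 1)`, which avoids exact-zero p-values; the default
#' follows the strict unsmoothed rule.
#'
#' @param A,B Nonempty numeric samples.
#' @param n_boot Number of bootstrap replicates (default 10,000).
#' @param seed Integer seed for the resampling, or `NULL`.
#' @param smoothed Use the add-one p-value estimate.
#' @return A `bootstrap_result`: `delta_mu`, `p_value`, `sig_level` (the
#'   strictest of 0.05 / 0.01 / 0.0001 with `p < level`, else `NA`),
#'   `null_quantiles` of the `delta_mu*` distribution, sample sizes,
#'   `n_boot`, `seed`, and the group means with standard errors.
#' @examples
#' bootstrap_mean_test(rnorm(20), rnorm(20, 1), n_boot = 1000, seed = 1)
#' @export
bootstrap_mean_test <- function(A, B, n_boot = 10000, seed = NULL,
                                smoothed = FALSE) {
  A <- as.numeric(A[!is.na(A)]); B <- as.numeric(B[!is.na(B)])
  if (length(A) == 0 || length(B) == 0)
    stop("`A` and `B` must be nonempty")
  if (n_boot < 1) stop("`n_boot` must be >= 1")
  # sorting makes the pool canonical, so test(A, B) and test(B, A) consume
  # identical resampling streams under the same seed
  pool <- sort(c(A, B))
  if (stats::sd(pool) == 0)
    warning("zero-variance pool: every delta_mu* is zero", call. = FALSE)
  k <- min(length(A), length(B))
  delta_mu <- abs(mean(A) - mean(B))
  dstar <- with_local_seed(seed, {
    draws <- matrix(pool[sample.int(length(pool), 2 * n_boot * k,
                                    replace = TRUE)], n_boot, 2 * k)
    abs(rowMeans(draws[, seq_len(k), drop = FALSE]) -
          rowMeans(draws[, k + seq_len(k), drop = FALSE]))
  })
  exceed <- sum(dstar > delta_mu)
  p <- if (smoothed) (exceed + 1) / (n_boot + 1) else exceed / n_boot
  structure(
    list(delta_mu = delta_mu, p_value = p,
         sig_level = significance_level(p),
         null_quantiles = stats::quantile(dstar,
                                          c(0.5, 0.9, 0.95, 0.99, 0.999)),
         n_a = length(A), n_b = length(B), n_draw = k,
         n_boot = as.integer(n_boot), seed = seed, smoothed = smoothed,
         mean_a = mean(A), mean_b = mean(B),
         sem_a = stats::sd(A) / sqrt(length(A)),
         sem_b = stats::sd(B) / sqrt(length(B))),
    class = "bootstrap_result"
  )
}

#' Significance category for a bootstrap p-value
#'
#' The strictest of the 5%, 1% and 0.01% levels with `p < level`
#' (strict), or `NA` when none applies.
#'
#' @param p A p-value in `[0, 1]`.
#' @return One of `0.05`, `0.01`, `1e-4`, or `NA_real_`.
#' @export
significance_level <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  levels <- c(1e-4, 0.01, 0.05)
  hit <- levels[p < levels]
  if (length(hit) == 0) NA_real_ else hit[1]
}

#' @export
print.bootstrap_result <- function(x, ...) {
  stars <- if (is.na(x$sig_level)) "n.s."
  else c("0.05" = "*", "0.01" = "**", "1e-04" = "***")[format(x$sig_level)]
  cat(sprintf(
    "Bootstrap mean test: |dmu| = %.4g, p = %.4g (%s)\n", x$delta_mu,
    x$p_value, stars))
  cat(sprintf("  A: n = %d, mean = %.4g +/- %.3g SEM\n", x$n_a, x$mean_a,
              x$sem_a))
  cat(sprintf("  B: n = %d, mean = %.4g +/- %.3g SEM\n", x$n_b, x$mean_b,
              x$sem_b))
  cat(sprintf("  %d replicates of size %d drawn from the pooled null\n",
              x$n_boot, x$n_draw))
  invisible(x)
}
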