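#' Percentile-bootstrap confidence interval for a median
#'
#' Resamples the values with replacement `n_boot` times, takes the median
#' of each resample, and returns the empirical `alpha/2` and
#' `1 - alpha/2` percentiles of the resampled medians (inverse-ECDF
#' quantiles, so the endpoints are always achievable resample medians).
#'
#' @param values Numeric vector with at least 2 values.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param alpha Significance level (default 0.05 for a 95% CI).
#' @param seed Integer seed.
#' @return An object of class `bootstrap_ci`: list with `median`, `lo`,
#'   `hi`, `n`, `n_boot`, `alpha`, `seed`.
#' @export
percentile_bootstrap_median <- function(values, n_boot = 10000L,
                                        alpha = 0.05, seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop_input("need at least 2 values to bootstrap")
  meds <- with_seed(seed, boot_medians(values, n_boot))
  ci <- quantile(meds, c(alpha / 2, 1 - alpha / 2), type = 1, names = FALSE)
  structure(list(median = median(values), lo = ci[1], hi = ci[2],
                 n = length(values), n_boot = as.integer(n_boot),
                 alpha = alpha,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("median %.4g, %g%% percentile-bootstrap CI [%.4g, %.4g] (n = %d, %d resamples)\n",
              x$median, 100 * (1 - x$alpha), x$lo, x$hi, x$n, x$n_boot))
  invisible(x)
}

# medians of n_boot with-replacement resamples; sorting once and indexing
# keeps this fast enough for the default 10,000 resamples
boot_medians <- function(values, n_boot) {
  n <- length(values)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  m <- matrix(values[idx], nrow = n)
  m <- apply(m, 2L, sort.int, method = "quick")
  if (n %% 2L == 1L) m[(n + 1L) %/% 2L, ]
  else (m[n %/% 2L, ] + m[n %/% 2L + 1L, ]) / 2
}

#' Three-way significance verdict from a difference CI
#'
#' Decision rule for a percentile-bootstrap CI around a difference of
#' medians (condition A - condition B): if both bounds are positive, A is
#' significantly higher; if both are negative, B is significantly higher;
#' if the interval straddles zero, no significance can be determined.
#'
#' @param lo,hi CI bounds with `lo <= hi`.
#' @return One of `"A_higher"`, `"B_higher"`, `"indeterminate"`.
#' @export
classify_significance <- function(lo, hi) {
  if (any(is.na(c(lo, hi)))) return("indeterminate")
  if (lo > hi) stop_input("'lo' must not exceed 'hi'")
  if (lo > 0 && hi > 0) "A_higher"
  else if (lo < 0 && hi < 0) "B_higher"
  else "indeterminate"
}

#' Bootstrap CI for a difference of medians between two conditions
#'
#' Independently resamples each group with replacement, computes the
#' difference of resample medians (A - B), and returns the percentile CI
#' with the three-way significance verdict of
#' [classify_significance()].
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each).
#' @param n_boot Number of bootstrap resamples.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @param feature,bin Optional labels carried into the result.
#' @return An object of class `comparison_result`: list with `feature`,
#'   `bin`, `diff_median` (median(A) - median(B)), `lo`, `hi`, `verdict`,
#'   `n_a`, `n_b`, `n_boot`, `alpha`.
#' @export
median_difference_ci <- function(values_a, values_b, n_boot = 10000L,
                                 alpha = 0.05, seed = NULL,
                                 feature = NA_character_,
                                 bin = NA_character_) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop_input("each group needs at least 2 values")
  diffs <- with_seed(seed, {
    boot_medians(values_a, n_boot) - boot_medians(values_b, n_boot)
  })
  ci <- quantile(diffs, c(alpha / 2, 1 - alpha / 2), type = 1, names = FALSE)
  structure(list(feature = feature, bin = bin,
                 diff_median = median(values_a) - median(values_b),
                 lo = ci[1], hi = ci[2],
                 verdict = classify_significance(ci[1], ci[2]),
                 n_a = length(values_a), n_b = length(values_b),
                 n_boot = as.integer(n_boot), alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  lab <- if (!is.na(x$feature)) paste0(x$feature,
                                       if (!is.na(x$bin)) paste0(" @ BSP ", x$bin) else "")
         else "difference of medians"
  cat(sprintf("%s: A - B = %.4g, %g%% CI [%.4g, %.4g] -> %s\n",
              lab, x$diff_median, 100 * (1 - x$alpha), x$lo, x$hi, x$verdict))
  invisible(x)
}
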