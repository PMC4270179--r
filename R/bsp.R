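#' Burst suppression ratio (BSR)
#'
#' Centered moving average of the binary suppression indicator over a
#' time window: the windowed fraction of time the EEG is suppressed,
#' between 0 (no suppression) and 1 (fully suppressed). Edges use the
#' available partial window.
#'
#' @param binary A [binary_series()].
#' @param window Averaging window in seconds; must be at least two
#'   sampling intervals.
#' @return Numeric vector in \[0, 1\], same length as the series.
#' @export
compute_bsr <- function(binary, window = 10) {
  stopifnot(inherits(binary, "binary_series"))
  if (!is.numeric(window) || length(window) != 1L || window < 2 * binary$delta)
    stop_input("'window' must be at least two sampling intervals (%g s)",
               2 * binary$delta)
  x <- binary$values
  n <- length(x)
  half <- max(1L, floor(window / binary$delta / 2))
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

default_bsp_params <- function(ci_level = 0.95) {
  list(sigma2_v = 1e-3, x0_mean = 0, x0_var = 1,
       em_tol = 1e-5, em_max_iter = 500L, ci_level = ci_level)
}

#' Forward filter of the BSP state-space model
#'
#' One forward pass of the Bernoulli random-walk model
#' `x_i = x_{i-1} + v_i`, `v_i ~ N(0, sigma2_v)`,
#' `b_i ~ Bernoulli(logistic(x_i))`. Each step predicts (mean carried,
#' variance inflated by `sigma2_v`) then updates to the posterior mode by
#' Newton iteration; the posterior variance uses the observed curvature
#' at the mode.
#'
#' @param binary A [binary_series()].
#' @param sigma2_v Process-noise variance (>= 0).
#' @param x0_mean,x0_var Initial state prior.
#' @return List with per-step `mean`, `var`, `pred_mean`, `pred_var`.
#' @export
bsp_forward_filter <- function(binary, sigma2_v = 1e-3,
                               x0_mean = 0, x0_var = 1) {
  stopifnot(inherits(binary, "binary_series"))
  if (sigma2_v < 0) stop_input("'sigma2_v' must be >= 0")
  if (x0_var <= 0) stop_input("'x0_var' must be > 0")
  bsp_filter_cpp(binary$values, sigma2_v, x0_mean, x0_var)
}

#' Fixed-interval smoother of the BSP state-space model
#'
#' Backward Rauch-Tung-Striebel pass: with gain
#' `A_i = var_{i|i} / pred_var_{i+1}`, the smoothed mean is
#' `x_{i|N} = x_{i|i} + A_i (x_{i+1|N} - pred_mean_{i+1})` and the
#' smoothed variance `var_{i|N} = var_{i|i} + A_i^2 (var_{i+1|N} -
#' pred_var_{i+1})`.
#'
#' @param filtered Output of [bsp_forward_filter()].
#' @return List with per-step smoothed `mean`, `var`, and lag-one
#'   covariances `cov1`.
#' @export
bsp_backward_smooth <- function(filtered) {
  bsp_smooth_cpp(filtered$mean, filtered$var,
                 filtered$pred_mean, filtered$pred_var)
}

# Exact posterior for the degenerate sigma2_v = 0 model: a single shared
# state x with prior N(x0_mean, x0_var) observed through n Bernoulli
# trials. Newton on the joint log posterior; Laplace variance at the mode.
bsp_shared_state_map <- function(b, x0_mean, x0_var) {
  n <- length(b)
  s <- sum(b)
  x <- x0_mean
  for (k in 1:200) {
    p <- plogis(x)
    g <- -(x - x0_mean) / x0_var + s - n * p
    h <- -1 / x0_var - n * p * (1 - p)
    xn <- x - g / h
    if (abs(xn - x) < 1e-12) { x <- xn; break }
    x <- xn
  }
  list(mean = x, var = 1 / (1 / x0_var + n * plogis(x) * (1 - plogis(x))))
}

#' Fit the burst suppression probability (BSP) model
#'
#' Estimates the instantaneous probability of EEG suppression from a
#' binary suppression series with the Bernoulli random-walk state-space
#' model, smoothing over the whole series and attaching pointwise
#' confidence intervals. The process-noise variance `sigma2_v` is fitted
#' by expectation maximization (EM) by default: each iteration runs the
#' forward filter and backward smoother, then sets `sigma2_v` to the
#' mean smoothed expectation of the squared state increments.
#'
#' A BSP of 1 indicates complete EEG suppression, 0 no suppression.
#' Confidence bounds are the logistic transform of the Gaussian state
#' posterior interval, so `0 < ci_lo <= bsp <= ci_hi < 1` always holds.
#'
#' Degenerate cases: if the series is all 0s or all 1s, `sigma2_v` is not
#' identifiable; EM is skipped with a warning and the model is fitted
#' with `sigma2_v = 0`. With `sigma2_v = 0` the model has a single shared
#' state, and the fit computes its exact posterior mode (the smoothed
#' trace is constant at the logistic-transformed MAP).
#'
#' @param binary A [binary_series()] (or 0/1 vector, taken at `delta`).
#' @param sigma2_v Initial (or fixed, if `em = FALSE`) process-noise
#'   variance.
#' @param x0_mean,x0_var Initial state prior (held fixed; sensitivity
#'   decays within ~100 steps).
#' @param em Fit `sigma2_v` by EM (default `TRUE`).
#' @param em_tol Relative convergence tolerance on `sigma2_v`.
#' @param em_max_iter EM iteration cap.
#' @param ci_level Confidence level for the pointwise intervals.
#' @param delta Sampling interval if `binary` is a plain vector.
#' @return An object of class `bsp`: list with `bsp`, `ci_lo`, `ci_hi`,
#'   `x_mean`, `x_var` (per step), `sigma2_v` (fitted), `n_iter`,
#'   `converged`, `binary`, `params`, `call`. Methods: `print`,
#'   `summary`, `coef`, `fitted`, `residuals`, `confint`, `plot`,
#'   `simulate`.
#' @examples
#' b <- generate_binary_series(rep(0.7, 2000), delta = 0.02, seed = 1)
#' fit <- bsp(b)
#' fit
#' head(fitted(fit))
#' @export
bsp <- function(binary, sigma2_v = 1e-3, x0_mean = 0, x0_var = 1,
                em = TRUE, em_tol = 1e-5, em_max_iter = 500L,
                ci_level = 0.95, delta = 0.02) {
  cl <- match.call()
  if (!inherits(binary, "binary_series")) binary <- binary_series(binary, delta)
  if (sigma2_v < 0) stop_input("'sigma2_v' must be >= 0")
  if (x0_var <= 0) stop_input("'x0_var' must be > 0")
  if (ci_level <= 0 || ci_level >= 1) stop_input("'ci_level' must be in (0, 1)")
  b <- binary$values
  n <- length(b)
  n_iter <- 0L
  converged <- TRUE
  if (em && (all(b == 0L) || all(b == 1L))) {
    warning("binary series is constant; sigma2_v is not identifiable - fitting with sigma2_v = 0")
    em <- FALSE
    sigma2_v <- 0
  }
  if (em) {
    em_step <- function(s2) {
      filt <- bsp_filter_cpp(b, s2, x0_mean, x0_var)
      sm <- bsp_smooth_cpp(filt$mean, filt$var, filt$pred_mean, filt$pred_var)
      i <- 2:n
      mean((sm$mean[i] - sm$mean[i - 1L])^2 +
             sm$var[i] + sm$var[i - 1L] - 2 * sm$cov1)
    }
    # plain EM on sigma2_v contracts geometrically with a ratio close to
    # 1 on long series; Aitken extrapolation over successive iterates
    # jumps to the fixed point in a few dozen steps
    hist3 <- c(NA_real_, NA_real_, sigma2_v)
    converged <- FALSE
    for (it in seq_len(em_max_iter)) {
      new_s2 <- em_step(sigma2_v)
      n_iter <- it
      if (abs(new_s2 - sigma2_v) <= em_tol * max(sigma2_v, 1e-12)) {
        sigma2_v <- new_s2
        converged <- TRUE
        break
      }
      hist3 <- c(hist3[2:3], new_s2)
      if (it %% 5L == 0L && !anyNA(hist3)) {
        d1 <- hist3[2] - hist3[1]
        d2 <- hist3[3] - hist3[2]
        if (is.finite(d2 - d1) && abs(d2 - d1) > 1e-18) {
          acc <- hist3[3] - d2^2 / (d2 - d1)
          if (is.finite(acc) && acc > 0) {
            new_s2 <- acc
            hist3 <- c(NA_real_, NA_real_, acc)
          }
        }
      }
      sigma2_v <- new_s2
    }
  }
  if (sigma2_v == 0) {
    map <- bsp_shared_state_map(b, x0_mean, x0_var)
    xs <- rep(map$mean, n)
    vs <- rep(map$var, n)
  } else {
    filt <- bsp_filter_cpp(b, sigma2_v, x0_mean, x0_var)
    sm <- bsp_smooth_cpp(filt$mean, filt$var, filt$pred_mean, filt$pred_var)
    xs <- sm$mean
    vs <- sm$var
  }
  z <- qnorm(1 - (1 - ci_level) / 2)
  structure(list(bsp = plogis(xs),
                 ci_lo = plogis(xs - z * sqrt(vs)),
                 ci_hi = plogis(xs + z * sqrt(vs)),
                 x_mean = xs, x_var = vs,
                 sigma2_v = sigma2_v, n_iter = n_iter, converged = converged,
                 binary = binary,
                 params = list(x0_mean = x0_mean, x0_var = x0_var,
                               em = em, em_tol = em_tol,
                               em_max_iter = em_max_iter,
                               ci_level = ci_level),
                 call = cl),
            class = "bsp")
}

#' EM fit of the BSP model (spec-style alias)
#'
#' @param binary A [binary_series()].
#' @param params List of model parameters (`sigma2_v`, `x0_mean`,
#'   `x0_var`, `em_tol`, `em_max_iter`, `ci_level`); missing entries take
#'   the defaults of [bsp()].
#' @return A `bsp` fit; see [bsp()].
#' @export
bsp_em_fit <- function(binary, params = list()) {
  p <- utils::modifyList(default_bsp_params(), params)
  bsp(binary, sigma2_v = p$sigma2_v, x0_mean = p$x0_mean, x0_var = p$x0_var,
      em = TRUE, em_tol = p$em_tol, em_max_iter = p$em_max_iter,
      ci_level = p$ci_level)
}

#' Estimate the BSP with default settings
#'
#' Convenience wrapper around [bsp()] with the default prior
#' (`x0_mean = 0`, `x0_var = 1`) and `sigma2_v` initialized at 1e-3.
#'
#' @param binary A [binary_series()].
#' @return A `bsp` fit.
#' @export
estimate_bsp <- function(binary) bsp(binary)

#' @export
print.bsp <- function(x, ...) {
  cat("Burst suppression probability (state-space Bernoulli smoother)\n")
  cat(sprintf("  n = %d steps @ %g s; sigma2_v = %.3g (%s, %d EM iterations)\n",
              length(x$bsp), x$binary$delta, x$sigma2_v,
              if (x$params$em) "EM" else "fixed", x$n_iter))
  cat(sprintf("  BSP: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$bsp), min(x$bsp), max(x$bsp)))
  invisible(x)
}

#' @export
summary.bsp <- function(object, ...) {
  out <- list(n = length(object$bsp), delta = object$binary$delta,
              sigma2_v = object$sigma2_v, n_iter = object$n_iter,
              converged = object$converged,
              ci_level = object$params$ci_level,
              bsp_quantiles = quantile(object$bsp, c(0, .25, .5, .75, 1)),
              mean_ci_width = mean(object$ci_hi - object$ci_lo),
              suppression_fraction = mean(object$binary$values))
  class(out) <- "summary.bsp"
  out
}

#' @export
print.summary.bsp <- function(x, ...) {
  cat("BSP model summary\n")
  cat(sprintf("  steps: %d (delta = %g s); observed suppression fraction %.3f\n",
              x$n, x$delta, x$suppression_fraction))
  cat(sprintf("  sigma2_v = %.4g (%d EM iterations%s)\n", x$sigma2_v, x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  cat("  BSP quantiles:\n")
  print(round(x$bsp_quantiles, 4))
  cat(sprintf("  mean %g%% CI width: %.4f\n", 100 * x$ci_level,
              x$mean_ci_width))
  invisible(x)
}

#' @export
coef.bsp <- function(object, ...) {
  c(sigma2_v = object$sigma2_v,
    x0_mean = object$params$x0_mean, x0_var = object$params$x0_var)
}

#' @export
fitted.bsp <- function(object, ...) object$bsp

#' @export
residuals.bsp <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$binary$values - object$bsp
  if (type == "pearson") r <- r / sqrt(object$bsp * (1 - object$bsp))
  r
}

#' @export
confint.bsp <- function(object, parm, level, ...) {
  cbind(lo = object$ci_lo, hi = object$ci_hi)
}

#' @export
plot.bsp <- function(x, ..., show_data = TRUE) {
  t <- (seq_along(x$bsp) - 1L) * x$binary$delta
  plot(t, x$bsp, type = "n", ylim = c(0, 1),
       xlab = "time (s)", ylab = "BSP", ...)
  polygon(c(t, rev(t)), c(x$ci_lo, rev(x$ci_hi)),
          col = "grey85", border = NA)
  if (show_data)
    graphics::points(t, x$binary$values, pch = ".", col = "grey55")
  lines(t, x$bsp, lwd = 2)
  invisible(x)
}

#' @export
simulate.bsp <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    replicate(nsim,
              binary_series(rbinom(length(object$bsp), 1L, object$bsp),
                            object$binary$delta),
              simplify = FALSE)
  })
}
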