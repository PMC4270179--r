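test_that("BSR endpoints and window semantics match the definition", {
  ones <- binary_series(rep(1, 200), 0.02)
  zeros <- binary_series(rep(0, 200), 0.02)
  expect_equal(compute_bsr(ones, 1), rep(1, 200))
  expect_equal(compute_bsr(zeros, 1), rep(0, 200))

  alt <- binary_series(rep(c(0, 1), 100), 0.02)
  bsr <- compute_bsr(alt, window = 200 * 0.02)
  expect_equal(mean(bsr), 0.5, tolerance = 0.01)
  expect_equal(bsr[100], 0.5, tolerance = 0.01)

  expect_error(compute_bsr(ones, 0.01), "two sampling intervals")
  expect_true(all(compute_bsr(alt, 0.5) >= 0 & compute_bsr(alt, 0.5) <= 1))
})

test_that("forward filter matches the pure-R reference recursions", {
  set.seed(14)
  for (k in 1:20) {
    n <- sample(20:200, 1)
    b <- rbinom(n, 1, runif(1, 0.2, 0.8))
    s2 <- sample(c(0, 1e-4, 1e-2, 0.5), 1)
    filt <- bsp_forward_filter(binary_series(b, 0.02), sigma2_v = s2)
    ref <- ref_bsp_filter(b, s2)
    expect_equal(filt$mean, ref$mean, tolerance = 1e-7)
    expect_equal(filt$var, ref$var, tolerance = 1e-7)
  }
})

test_that("filtered probability accumulates evidence monotonically (sigma2_v = 0)", {
  b <- binary_series(rep(1, 500), 0.02)
  filt <- bsp_forward_filter(b, sigma2_v = 0)
  p <- plogis(filt$mean)
  expect_true(all(diff(p) > -1e-12))
  expect_gt(p[500], 0.95)
})

test_that("a single update solves the scalar mode equation", {
  # flat-ish prior (0, 1), sigma2_v = 0, observation b = 1:
  # the mode solves x = 1 - logistic(x)
  filt <- bsp_forward_filter(binary_series(1L, 0.02), sigma2_v = 0,
                             x0_mean = 0, x0_var = 1)
  oracle <- bisect_mode(0, 1, 1)
  expect_equal(filt$mean[1], oracle, tolerance = 1e-8)
  expect_equal(oracle + plogis(oracle), 1, tolerance = 1e-8)
})

test_that("terminal filtered probability concentrates at the empirical rate", {
  set.seed(21)
  b <- rbinom(10000, 1, 0.6)
  filt <- bsp_forward_filter(binary_series(b, 0.02), sigma2_v = 0)
  expect_equal(plogis(filt$mean[10000]), 0.6, tolerance = 0.02 / 0.6)
})

test_that("smoother initialization, zero-noise constancy and variance ordering", {
  set.seed(31)
  b <- rbinom(300, 1, 0.5)
  filt <- bsp_forward_filter(binary_series(b, 0.02), sigma2_v = 1e-3)
  sm <- bsp_backward_smooth(filt)
  n <- length(b)
  expect_equal(sm$mean[n], filt$mean[n])
  expect_equal(sm$var[n], filt$var[n])

  filt0 <- bsp_forward_filter(binary_series(b, 0.02), sigma2_v = 0)
  sm0 <- bsp_backward_smooth(filt0)
  expect_lt(diff(range(sm0$mean)), 1e-8)

  # smoothed variances never exceed filtered variances (100 random inputs)
  for (k in 1:100) {
    bb <- rbinom(sample(10:80, 1), 1, runif(1, 0.1, 0.9))
    f <- bsp_forward_filter(binary_series(bb, 0.02),
                            sigma2_v = sample(c(1e-4, 1e-2, 0.3), 1))
    s <- bsp_backward_smooth(f)
    expect_true(all(s$var <= f$var + 1e-12))
  }
})

test_that("smoother agrees with the pure-R reference", {
  set.seed(17)
  b <- rbinom(150, 1, 0.4)
  filt <- bsp_forward_filter(binary_series(b, 0.02), sigma2_v = 5e-3)
  sm <- bsp_backward_smooth(filt)
  ref <- ref_bsp_smooth(ref_bsp_filter(b, 5e-3))
  expect_equal(sm$mean, ref$mean, tolerance = 1e-6)
  expect_equal(sm$var, ref$var, tolerance = 1e-6)
})

test_that("complete suppression drives the fitted BSP to 1", {
  b <- binary_series(rep(1, 5000), 0.02)
  expect_warning(fit <- bsp(b), "constant")
  expect_gte(fit$bsp[2500], 0.99)
  expect_equal(round(fit$bsp[2500], 2), 1)
  expect_equal(fit$sigma2_v, 0)

  expect_warning(fit0 <- bsp(binary_series(rep(0, 5000), 0.02)), "constant")
  expect_lte(fit0$bsp[2500], 0.01)
})

test_that("EM recovers a slow logistic random walk (RMSE and coverage)", {
  res <- vapply(1:5, function(k) {
    set.seed(104 + k)
    n <- 10000
    x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(1e-4))))
    p <- plogis(x)
    b <- rbinom(n, 1, p)
    fit <- bsp(binary_series(b, 0.02))
    c(rmse = sqrt(mean((fit$bsp - p)^2)),
      cov = mean(fit$ci_lo <= p & p <= fit$ci_hi),
      conv = fit$converged)
  }, numeric(3))
  expect_lt(median(res["rmse", ]), 0.05)
  expect_gte(median(res["cov", ]), 0.90)
  expect_true(all(res["conv", ] == 1))
})

test_that("BSP with sigma2_v = 0 matches a grid-search MAP oracle", {
  set.seed(55)
  for (rate in c(0.3, 0.6, 0.8)) {
    b <- rbinom(2000, 1, rate)
    fit <- bsp(binary_series(b, 0.02), sigma2_v = 0, em = FALSE)
    grid <- seq(-10, 10, length.out = 400001)
    loglik <- -grid^2 / 2 + sum(b) * grid - length(b) * log1p(exp(grid))
    p_map <- plogis(grid[which.max(loglik)])
    expect_equal(fit$bsp[1000], p_map, tolerance = 1e-4)
    expect_lt(diff(range(fit$bsp)), 1e-12)
  }
})

test_that("fits are deterministic and respect the trace bounds invariant", {
  set.seed(61)
  b <- binary_series(rbinom(800, 1, 0.55), 0.02)
  f1 <- bsp(b)
  f2 <- bsp(b)
  expect_identical(f1$bsp, f2$bsp)
  expect_identical(f1$sigma2_v, f2$sigma2_v)
  for (f in list(f1, bsp(b, sigma2_v = 1e-2, em = FALSE))) {
    expect_true(all(f$ci_lo > 0 & f$ci_hi < 1))
    expect_true(all(f$ci_lo <= f$bsp & f$bsp <= f$ci_hi))
    expect_equal(length(f$bsp), 800L)
  }
})

test_that("windowed mean BSP is monotone in the evidence", {
  set.seed(71)
  for (k in 1:50) {
    n <- 300
    b <- rbinom(n, 1, runif(1, 0.3, 0.7))
    win <- 120:180
    zeros <- intersect(win, which(b == 0))
    if (length(zeros) < 3) next
    b2 <- b
    b2[sample(zeros, 3)] <- 1L
    f1 <- bsp(binary_series(b, 0.02), sigma2_v = 1e-3, em = FALSE)
    f2 <- bsp(binary_series(b2, 0.02), sigma2_v = 1e-3, em = FALSE)
    expect_gte(mean(f2$bsp[win]), mean(f1$bsp[win]) - 1e-10)
  }
})

test_that("bsp_em_fit and estimate_bsp wrap the model with spec defaults", {
  set.seed(81)
  b <- binary_series(rbinom(500, 1, 0.5), 0.02)
  f1 <- bsp_em_fit(b)
  expect_s3_class(f1, "bsp")
  expect_true(f1$params$em)
  f2 <- estimate_bsp(b)
  expect_identical(f1$bsp, f2$bsp)
})

test_that("bsp methods behave like a classed model fit", {
  set.seed(91)
  b <- binary_series(rbinom(400, 1, 0.6), 0.02)
  fit <- bsp(b)
  expect_output(print(fit), "Burst suppression probability")
  expect_output(print(summary(fit)), "sigma2_v")
  expect_named(coef(fit), c("sigma2_v", "x0_mean", "x0_var"))
  expect_identical(fitted(fit), fit$bsp)
  expect_equal(residuals(fit), b$values - fit$bsp)
  rp <- residuals(fit, type = "pearson")
  expect_equal(rp, (b$values - fit$bsp) / sqrt(fit$bsp * (1 - fit$bsp)))
  ci <- confint(fit)
  expect_equal(unname(ci[, 1]), fit$ci_lo)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "binary_series")
  expect_identical(simulate(fit, seed = 5)[[1]]$values, sims[[1]]$values)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("invalid BSP inputs raise parameter errors", {
  b <- binary_series(c(0, 1, 1), 0.02)
  expect_error(bsp(b, sigma2_v = -1), ">= 0")
  expect_error(bsp(b, x0_var = 0), "> 0")
  expect_error(bsp(b, ci_level = 1.2), "\\(0, 1\\)")
  expect_error(binary_series(c(0, 2), 0.02), "0/1")
  expect_error(binary_series(integer(0), 0.02), "0/1|nonempty")
})
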