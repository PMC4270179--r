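test_that("nonlinear energy operator matches its closed forms", {
  fs <- 100
  const <- recording(rep(3, 50), fs)
  expect_equal(nleo(const)$values, rep(0, 50))

  # linear ramp x(n) = 2n + 5 -> psi = slope^2 = 4 everywhere
  ramp <- recording(2 * (1:50) + 5, fs)
  expect_equal(nleo(ramp)$values, rep(4, 50))

  # x(n) = A sin(w n), A = 2, w = pi/2 -> psi = A^2 sin^2(w) = 4
  n <- 1:64
  sine <- recording(2 * sin(pi / 2 * n), fs)
  expect_equal(nleo(sine)$values, rep(4, 64), tolerance = 1e-12)

  expect_error(nleo(recording(c(1, 2), fs)), "3 samples")
})

test_that("nleo equals the brute-force definition on random signals", {
  set.seed(42)
  for (k in 1:1000) {
    n <- sample(3:40, 1)
    x <- rnorm(n, sd = sample(c(0.1, 1, 50), 1))
    psi <- nleo(recording(x, 100))$values
    i <- 2:(n - 1)
    expect_identical(psi[i], x[i]^2 - x[i - 1] * x[i + 1])
    expect_identical(psi[1], psi[2])
    expect_identical(psi[n], psi[n - 1])
  }
})

test_that("threshold_labels splits on the energy threshold", {
  e <- structure(list(values = c(1, 5, 0.2, 9), fs = 50, start_time = 0),
                 class = "energy_series")
  expect_equal(threshold_labels(e, 10), rep("suppression", 4))
  expect_equal(threshold_labels(e, 0.1), rep("burst", 4))
  expect_equal(threshold_labels(e, 2),
               c("suppression", "burst", "suppression", "burst"))
  expect_error(threshold_labels(e, -1), "positive")
})

test_that("suggest_threshold splits well-separated log-normal modes", {
  set.seed(7)
  v <- c(exp(rnorm(4000, log(5), 0.5)), exp(rnorm(6000, log(2000), 0.5)))
  truth <- rep(c("suppression", "burst"), c(4000, 6000))
  e <- structure(list(values = v, fs = 50, start_time = 0),
                 class = "energy_series")
  for (m in c("mixture", "otsu")) {
    th <- suggest_threshold(e, method = m)
    lab <- ifelse(v > th, "burst", "suppression")
    expect_lt(mean(lab != truth), 0.02)
  }
})

test_that("suggest_threshold warns and returns midpoint on degenerate energy", {
  e <- structure(list(values = rep(3, 100), fs = 50, start_time = 0),
                 class = "energy_series")
  expect_warning(th <- suggest_threshold(e), "degenerate")
  expect_equal(th, 3, tolerance = 1e-6)
})

test_that("events round-trip through run-length encoding", {
  labs <- c("suppression", "suppression", "burst", "burst", "burst")
  ev <- events_from_labels(labs, fs = 1)
  expect_equal(ev$label, c("suppression", "burst"))
  expect_equal(ev$start, c(0, 2))
  expect_equal(ev$end, c(2, 5))

  one <- events_from_labels(rep("burst", 10), fs = 5)
  expect_equal(nrow(one), 1L)
  expect_equal(one$end, 2)

  # events -> labels -> events is the identity on tilings
  set.seed(3)
  labs2 <- rep(sample(c("burst", "suppression"), 30, replace = TRUE),
               sample(1:10, 30, replace = TRUE))
  ev2 <- events_from_labels(labs2, fs = 50)
  back <- rep(ev2$label, round((ev2$end - ev2$start) * 50))
  expect_identical(events_from_labels(back, fs = 50), ev2)

  expect_error(events_from_labels(character(0), 50), "nonempty")
})

test_that("minimum-duration filter uses the strict shorter-than rule", {
  ev <- data.frame(label = c("burst", "suppression", "burst"),
                   start = c(0, 0.10, 0.25),
                   end = c(0.10, 0.25, 0.45))
  kept <- filter_min_duration(ev, 0.15)
  expect_equal(kept$start, c(0.10, 0.25))  # 0.10 s dropped
  expect_equal(nrow(filter_min_duration(ev, 0)), 3L)
  # an event of exactly 0.15 s is retained
  expect_equal(nrow(filter_min_duration(
    data.frame(label = "burst", start = 0, end = 0.15), 0.15)), 1L)
  # 0.20 s retained
  expect_equal(nrow(filter_min_duration(
    data.frame(label = "burst", start = 0, end = 0.20), 0.15)), 1L)
  expect_error(filter_min_duration(ev, -1), ">= 0")
})

test_that("merge_short_runs removes interior fragments only", {
  labs <- rep(c("burst", "suppression", "burst"), c(40, 3, 40))
  out <- merge_short_runs(labs, fs = 50, min_dur = 0.15)
  expect_equal(out, rep("burst", 83))
  # edge runs are untouched
  labs2 <- rep(c("suppression", "burst"), c(2, 50))
  expect_equal(merge_short_runs(labs2, 50), labs2)
  # long runs pass through unchanged
  labs3 <- rep(c("burst", "suppression"), c(20, 20))
  expect_identical(merge_short_runs(labs3, 50), labs3)
})

test_that("binarize codes suppression as 1 with delta = 1/fs", {
  expect_equal(binarize(rep("suppression", 5), 50)$values, rep(1L, 5))
  expect_equal(binarize(rep("burst", 5), 50)$values, rep(0L, 5))
  labs <- c("burst", "suppression", "suppression", "burst")
  b <- binarize(labs, 50)
  expect_equal(mean(b$values), mean(labs == "suppression"))
  expect_equal(b$delta, 1 / 50)
})

test_that("segmentation recovers >= 95% of true labels on default profiles", {
  for (prof in list(sevoflurane_profile(), propofol_profile())) {
    synth <- generate_recording(prof, 200, fs = 500, seed = 21)
    expect_gt(segmentation_accuracy(synth), 0.95)
  }
})

test_that("segmentation events alternate and tile; filtering never overlaps", {
  synth <- generate_recording(propofol_profile(), 60, fs = 500, seed = 13)
  cond <- preprocess(synth$recording, smooth_sigma = NULL)
  seg <- segment_recording(cond)
  ev <- seg$events
  expect_true(all(ev$end > ev$start))
  expect_true(all(ev$label[-1] != ev$label[-nrow(ev)]))
  expect_equal(ev$start[-1], ev$end[-nrow(ev)])
  evf <- seg$events_filtered
  if (nrow(evf) > 1)
    expect_true(all(evf$start[-1] >= evf$end[-nrow(evf)] - 1e-12))
  # binary series is built from the raw labels
  expect_equal(seg$binary$values, as.integer(seg$labels == "suppression"))
})
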