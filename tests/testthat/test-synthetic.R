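test_that("alternating renewal sampling is seeded, alternating and truncated", {
  prof <- sevoflurane_profile()
  e1 <- sample_alternating_renewal(prof, 200, seed = 4)
  e2 <- sample_alternating_renewal(prof, 200, seed = 4)
  expect_identical(e1, e2)
  expect_equal(e1$label[1], "burst")
  expect_true(all(e1$label[-1] != e1$label[-nrow(e1)]))
  expect_equal(e1$start[-1], e1$end[-nrow(e1)])  # tiling, no gaps
  expect_equal(max(e1$end), 200)

  # truncation: a total shorter than any plausible first event
  e3 <- sample_alternating_renewal(prof, 1e-4, seed = 1)
  expect_equal(nrow(e3), 1L)
  expect_equal(e3$end, 1e-4)

  expect_error(sample_alternating_renewal(prof, -5), "positive")
})

test_that("long-run suppression fraction matches the renewal-theory limit", {
  # E[supp] = 3 s, E[burst] = 1 s -> fraction E[S]/(E[S]+E[B]) = 0.75
  prof <- drug_profile("test", 2, 0.5, 2, 1.5, burst_amp = 100, supp_amp = 20)
  ev <- sample_alternating_renewal(prof, 2000, seed = 8)
  supp_time <- sum((ev$end - ev$start)[ev$label == "suppression"])
  expect_equal(supp_time / 2000, 0.75, tolerance = 0.03 / 0.75)

  # convergence within 3 standard errors over 20 seeded replicates:
  # SE of the time fraction ~ sd(cycle contribution)/sqrt(n_cycles)
  fr <- vapply(1:20, function(s) {
    e <- sample_alternating_renewal(prof, 500, seed = 100 + s)
    sum((e$end - e$start)[e$label == "suppression"]) / 500
  }, numeric(1))
  n_cycles <- 500 / 4
  se <- sd(fr)
  expect_true(all(abs(fr - 0.75) < 3 * pmax(se, 0.02)))
})

test_that("rendered waveforms have the profiled band content and RMS contrast", {
  prof <- sevoflurane_profile()
  ev <- sample_alternating_renewal(prof, 120, seed = 5)
  rec <- render_waveform(ev, prof, fs = 500, seed = 6)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(length(rec$samples), 120 * 500)

  lab <- with(ev, label[pmax(findInterval((seq_along(rec$samples) - 0.5) / 500,
                                          start), 1L)])
  # drop samples near transitions so tapers don't blur the comparison
  bnd <- sort(unique(c(ev$start, ev$end)))
  t <- (seq_along(rec$samples) - 0.5) / 500
  away <- vapply(t, function(tt) min(abs(tt - bnd)) > 0.1, logical(1))

  rms_b <- sqrt(mean(rec$samples[lab == "burst" & away]^2))
  rms_s <- sqrt(mean(rec$samples[lab == "suppression" & away]^2))
  expect_equal(rms_b / rms_s, prof$burst_amp / prof$supp_amp, tolerance = 0.1)

  # >= 80% of burst spectral power inside the profile band
  xb <- rec$samples[lab == "burst" & away]
  spec <- Mod(fft(xb * 2 / length(xb)))^2
  freq <- (seq_along(spec) - 1) * 500 / length(spec)
  half <- freq <= 250
  inband <- freq >= prof$burst_band_lo & freq <= prof$burst_band_hi & half
  expect_gt(sum(spec[inband]) / sum(spec[half]), 0.8)

  # empty event list -> zero-length recording
  e0 <- ev[0, ]
  expect_equal(length(render_waveform(e0, prof, 500)$samples), 0L)

  # Nyquist violation
  expect_error(render_waveform(ev, prof, fs = 15), "Nyquist")
})

test_that("generate_binary_series draws seeded Bernoulli indicators", {
  expect_equal(generate_binary_series(rep(1, 50), seed = 1)$values, rep(1L, 50))
  expect_equal(generate_binary_series(rep(0, 50), seed = 1)$values, rep(0L, 50))
  b <- generate_binary_series(rep(0.6, 10000), seed = 3)
  expect_equal(mean(b$values), 0.6, tolerance = 0.015 / 0.6)
  expect_identical(b$values, generate_binary_series(rep(0.6, 10000), seed = 3)$values)
  expect_error(generate_binary_series(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("generated recordings carry consistent ground truth", {
  synth <- generate_recording(propofol_profile(), 60, fs = 500, seed = 2)
  ev <- synth$truth$events
  expect_equal(ev$start[-1], ev$end[-nrow(ev)])
  expect_equal(length(synth$truth$labels), length(synth$recording$samples))
  expect_true(all(synth$truth$p_true >= 0 & synth$truth$p_true <= 1))
  # labels agree with the event list at sample midpoints
  t <- (seq_along(synth$truth$labels) - 0.5) / 500
  expect_identical(synth$truth$labels,
                   ev$label[pmax(findInterval(t, ev$start), 1L)])

  # bit-reproducible under the same seed; different under another seed
  again <- generate_recording(propofol_profile(), 60, fs = 500, seed = 2)
  expect_identical(synth$recording$samples, again$recording$samples)
  other <- generate_recording(propofol_profile(), 60, fs = 500, seed = 3)
  expect_false(identical(synth$recording$samples, other$recording$samples))
  # ... but with comparable summary statistics
  expect_equal(sd(other$recording$samples), sd(synth$recording$samples),
               tolerance = 0.15)
})

test_that("profile invariants are enforced", {
  expect_error(drug_profile("x", 2, 0.5, 2, 1, burst_amp = 10, supp_amp = 20),
               "exceed")
  expect_error(drug_profile("x", 2, -0.5, 2, 1, burst_amp = 30, supp_amp = 20),
               "positive")
  expect_error(drug_profile("x", 2, 0.5, 2, 1, burst_amp = 30, supp_amp = 20,
                            burst_band_lo = 10, burst_band_hi = 5), "below")
})

test_that("sevoflurane-like events are longer than propofol-like after segmentation", {
  sev <- generate_recording(sevoflurane_profile(), 150, fs = 500, seed = 9)
  pro <- generate_recording(propofol_profile(), 150, fs = 500, seed = 9)
  med_dur <- function(synth, lab) {
    cond <- preprocess(synth$recording, smooth_sigma = NULL)
    seg <- segment_recording(cond)
    ev <- seg$events_filtered
    median((ev$end - ev$start)[ev$label == lab])
  }
  expect_gt(med_dur(sev, "suppression"), med_dur(pro, "suppression"))
  expect_gt(med_dur(sev, "burst"), med_dur(pro, "burst"))
})

test_that("rendered amplitude ordering always honors burst > suppression RMS", {
  for (s in 1:5) {
    prof <- propofol_profile()
    synth <- generate_recording(prof, 30, fs = 500, seed = s)
    lab <- truth_labels_at(synth, 500)
    x <- synth$recording$samples
    expect_gt(sqrt(mean(x[lab == "burst"]^2)),
              sqrt(mean(x[lab == "suppression"]^2)))
  }
})
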