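# burstkit

Quantification and comparison of EEG burst suppression in R.

Burst suppression is the EEG pattern of deep anesthesia (and several
pathologies): high-amplitude *bursts* alternate with low-amplitude
*suppressions*. Two anesthetics at the "same depth" can nonetheless
produce very different bursts and suppressions, so comparing them
requires (i) segmenting the EEG into events, (ii) quantifying the depth
of suppression on a common scale, and (iii) comparing event features at
matched depth. burstkit implements that full chain for single-channel
EEG, plus a seeded synthetic generator so the whole pipeline can be
exercised, tested and calibrated without access to animal recordings.

## What it computes

* **Segmentation.** The conditioned EEG (zero-phase 0.3–50 Hz band-pass,
  downsampling to 50 Hz, detrending, light Gaussian smoothing) is passed
  through the nonlinear energy operator (NLEO)

  ψ[x(n)] = x(n)² − x(n−1)·x(n+1),

  which responds to amplitude *and* frequency and separates bursts from
  suppressions cleanly in the energy domain. Samples above an energy
  threshold θ are bursts; below, suppressions. θ can be set manually
  (the reference procedure is visual) or automatically from a
  two-component mixture split of the log-energy distribution.

* **BSR and BSP.** The binarized EEG (1 = suppression) gives the burst
  suppression ratio (windowed moving average) and the burst suppression
  probability (BSP): a state-space model with a latent Gaussian random
  walk `x_i = x_{i−1} + v_i`, `v_i ~ N(0, σ_v²)` observed through
  `b_i ~ Bernoulli(logistic(x_i))`. A forward posterior-mode filter and
  fixed-interval smoother give the instantaneous probability of
  suppression with pointwise confidence intervals; σ_v² can be fitted by
  EM. BSP = 1 means complete suppression, 0 none. `bsp()` returns a
  classed model object with `print`, `summary`, `coef`, `fitted`,
  `residuals`, `confint`, `plot` and `simulate` methods.

* **Event features and inference.** Each burst or suppression lasting at
  least 0.15 s contributes its duration (s), peak-to-peak amplitude (μV)
  and power (10·log₁₀(Σx²/T), labeled dB μV²/s). Events are sorted by
  their mean BSP into bins 0.3–0.4, …, 0.7–0.8 and compared between two
  conditions per bin with the percentile bootstrap: medians with 95%
  CIs, the CI of the difference of medians, and a three-way verdict
  (A higher / B higher / indeterminate) from the signs of the difference
  CI.

* **Spectral analysis.** Multitaper spectrograms with Slepian (DPSS)
  tapers; defaults are 2 s windows stepped by 50 ms with 1 Hz
  half-bandwidth (K = 2TW − 1 = 3 tapers).

* **Synthetic data.** `generate_recording()` draws alternating
  burst/suppression sojourns from drug-specific gamma distributions,
  renders bursts as band-limited sustained oscillations and suppressions
  as low-pass background noise, and returns the recording together with
  per-sample ground-truth labels and the true suppression probability.
  The built-in `sevoflurane_profile()` (long, high-amplitude events) and
  `propofol_profile()` (short, low-amplitude events) are calibrated so
  segmented median peak-to-peak amplitudes land near the reported rodent
  values (sevoflurane suppressions ≈ 136 μV, propofol suppressions
  ≈ 52 μV, propofol bursts ≈ 196 μV).

## Worked example

```r
library(burstkit)

sev <- generate_recording(sevoflurane_profile(), 300, fs = 500, seed = 1)
pro <- generate_recording(propofol_profile(),    300, fs = 500, seed = 2)

cfg <- pipeline_config(seed = 42, log_level = "quiet")
report <- run_compare(sev$recording, pro$recording, cfg,
                      label_a = "sevoflurane-like", label_b = "propofol-like")
report
```

```
Burst-suppression comparison: sevoflurane-like vs propofol-like

Event counts per BSP bin:
     bin sevoflurane-like_bursts sevoflurane-like_suppressions
 0.3-0.4                       8                             5
 0.4-0.5                      22                            20
 0.5-0.6                      22                            21
 0.6-0.7                      19                            22
 0.7-0.8                       7                             9
   Total                      78                            77
 propofol-like_bursts propofol-like_suppressions
                   20                         18
                   25                         26
                   84                         79
                   45                         50
                   22                         23
                  196                        196

30 populated bin/label/feature comparisons:
     bin       label  feature median_a median_b    diff diff_lo diff_hi
 0.3-0.4       burst duration     3.45     0.86   2.590   1.870   3.740
 0.3-0.4       burst      p2p   565.79   205.68 360.110 350.713 370.250
 0.3-0.4       burst power_db    62.58    53.96   8.626   8.513   8.774
 ...
```

Reading the first row: in the lightest-suppression bin (BSP 0.3–0.4),
the median sevoflurane-like burst lasts 3.45 s against 0.86 s for the
propofol-like condition; the 95% bootstrap CI of the difference of
medians is [1.87, 3.74] s, entirely positive, so the verdict is
`A_higher` — sevoflurane-like bursts are significantly longer at matched
depth. The `p2p` rows make the same comparison for peak-to-peak
amplitude (565.8 vs 205.7 μV) and `power_db` for per-event power.
`write_report(report, "results/")` writes the count table, statistics
table, BSP traces, a YAML config snapshot and a log as tab-separated
text.

A runnable command-line wrapper with `synth`, `segment`, `bsp`,
`spectrogram` and `compare` subcommands is installed under
`inst/cli/burstkit.R`.

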