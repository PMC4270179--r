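# Shared helpers: reference (pure-R) state-space recursions used as the
# cross-check for the compiled filter/smoother, small constructors, and
# an accuracy helper for synthetic recordings.

ref_bsp_filter <- function(b, sigma2_v, x0_mean = 0, x0_var = 1) {
  n <- length(b)
  m <- v <- mp <- vp <- numeric(n)
  prev_m <- x0_mean
  prev_v <- x0_var
  for (i in seq_len(n)) {
    pm <- prev_m
    pv <- prev_v + sigma2_v
    mp[i] <- pm
    vp[i] <- pv
    # solve x = pm + pv * (b - logistic(x)) by bisection on the bracket
    lo <- pm + pv * (b[i] - 1)
    hi <- pm + pv * b[i]
    for (k in 1:200) {
      x <- (lo + hi) / 2
      f <- x - pm - pv * (b[i] - plogis(x))
      if (f > 0) hi <- x else lo <- x
      if (hi - lo < 1e-12) break
    }
    x <- (lo + hi) / 2
    p <- plogis(x)
    m[i] <- x
    v[i] <- 1 / (1 / pv + p * (1 - p))
    prev_m <- m[i]
    prev_v <- v[i]
  }
  list(mean = m, var = v, pred_mean = mp, pred_var = vp)
}

ref_bsp_smooth <- function(filt) {
  n <- length(filt$mean)
  xs <- vs <- numeric(n)
  xs[n] <- filt$mean[n]
  vs[n] <- filt$var[n]
  for (i in (n - 1):1) {
    A <- filt$var[i] / filt$pred_var[i + 1]
    xs[i] <- filt$mean[i] + A * (xs[i + 1] - filt$pred_mean[i + 1])
    vs[i] <- filt$var[i] + A^2 * (vs[i + 1] - filt$pred_var[i + 1])
  }
  list(mean = xs, var = vs)
}

# scalar posterior-mode equation solved by bisection (single-update oracle)
bisect_mode <- function(pm, pv, b, tol = 1e-12) {
  lo <- pm + pv * (b - 1)
  hi <- pm + pv * b
  while (hi - lo > tol) {
    x <- (lo + hi) / 2
    if (x - pm - pv * (b - plogis(x)) > 0) hi <- x else lo <- x
  }
  (lo + hi) / 2
}

# per-sample true labels of a synthetic recording at rate fs
truth_labels_at <- function(synth, fs) {
  t <- (seq_len(round(duration(synth$recording) * fs)) - 0.5) / fs
  ev <- synth$truth$events
  ev$label[pmax(findInterval(t, ev$start), 1L)]
}

segmentation_accuracy <- function(synth, fs_out = 50) {
  cond <- preprocess(synth$recording, smooth_sigma = NULL, fs_out = fs_out)
  seg <- segment_recording(cond)
  truth <- truth_labels_at(synth, fs_out)
  mean(truth == seg$labels)
}

make_recording <- function(f_hz, fs = 500, dur = 10, amp = 1) {
  recording(amp * sin(2 * pi * f_hz * (0:(dur * fs - 1)) / fs), fs)
}
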