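# Shared fixture builders. Everything is generated in code at test time.

# A recording made of per-second tiles: `freqs` gives the sinusoid frequency
# for each 1-s bin, recycled to the requested duration.
tiled_sine_recording <- function(freqs, duration_s, fs = 1000, amp = 50) {
  n_bins <- duration_s
  freqs <- rep_len(freqs, n_bins)
  x <- unlist(lapply(freqs, function(f) {
    tt <- (0:(fs - 1)) / fs
    amp * sin(2 * pi * f * tt)
  }))
  recording(matrix(x, nrow = 1), fs = fs)
}

# White noise with `n_bursts` 120-Hz bursts (100 ms) injected at known
# sample positions; returns recording + 0-based half-open truth intervals.
burst_benchmark <- function(n_bursts = 50, duration_s = 300, fs = 1000,
                            noise_sd = 5, burst_amp = 50, seed = 1) {
  set.seed(seed)
  n <- duration_s * fs
  x <- rnorm(n, 0, noise_sd)
  starts <- round(seq(5, duration_s - 5, length.out = n_bursts) * fs)
  len <- round(0.1 * fs)
  for (s in starts) {
    idx <- s:(s + len - 1)
    x[idx] <- x[idx] + burst_amp * cos(2 * pi * 120 * (seq_len(len) - 1) / fs)
  }
  list(recording = recording(matrix(x, nrow = 1), fs = fs),
       truth = cbind(start = starts - 1L, end = starts + len - 1L))
}

# recall/precision of detected events against truth intervals (overlap rule)
event_recall_precision <- function(events, truth) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(events$start < truth[i, "end"] & events$end > truth[i, "start"])
  }, logical(1))
  tp <- if (nrow(events) == 0) logical(0) else
    vapply(seq_len(nrow(events)), function(i) {
      any(truth[, "start"] < events$end[i] & truth[, "end"] > events$start[i])
    }, logical(1))
  c(recall = mean(hit),
    precision = if (length(tp) == 0) NA_real_ else mean(tp))
}

# a carrier recording gated at a duty cycle (1 = continuous), 1-s period
gated_carrier_recording <- function(duty, duration_s = 300, fs = 1000,
                                    amp = 25, noise_sd = 5, seed = 1) {
  set.seed(seed)
  n <- duration_s * fs
  tt <- (0:(n - 1)) / fs
  gate <- if (duty >= 1) rep(1, n) else {
    g <- numeric(n)
    on <- round(duty * fs)
    for (k in seq(1, n, by = fs)) g[k:min(k + on - 1, n)] <- 1
    g
  }
  recording(matrix(amp * cos(2 * pi * 120 * tt) * gate +
                     rnorm(n, 0, noise_sd), nrow = 1), fs = fs)
}

# flat (slope-0) single-biomarker cohort curves for calibration experiments
flat_mi_curves <- function(intercept = 0.3, noise_sd = 0.05) {
  data.frame(biomarker = "mi80_0.5_1",
             lobe = c("frontal", "temporal", "parietal", "occipital"),
             intercept = intercept, slope = 0, noise_sd = noise_sd)
}

# occipital-growth single-biomarker curves at the study's magnitudes
mi_only_curves <- function() {
  data.frame(biomarker = "mi80_0.5_1",
             lobe = c("frontal", "temporal", "parietal", "occipital"),
             intercept = 0.05,
             slope = c(0.0070, 0.0072, 0.011, 0.047),
             noise_sd = 0.05)
}

write_sites_fixture <- function(path, lobe = c("frontal", "Occipital",
                                               "temporal"),
                                x = c(10, -20, 30)) {
  lines <- c(
    "name\tsubject\tx\ty\tz\tlobe\themisphere\tis_soz\tis_spike_zone\tis_lesion",
    sprintf("e1\tsub01\t%s\t5\t5\t%s\tleft\t0\t0\t0", x[1], lobe[1]),
    sprintf("e2\tsub01\t%s\t6\t5\t%s\tleft\t1\t0\t0", x[2], lobe[2]),
    sprintf("e3\tsub02\t%s\t7\t5\t%s\tright\t0\t1\t0", x[3], lobe[3]))
  writeLines(lines, path)
  path
}
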