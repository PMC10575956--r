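# High-frequency oscillation (HFO) detection. Four threshold algorithms run
# on the f_cut-high-pass-filtered trace; every threshold is a relative
# statistic of that same trace (SD multiples, ECDF percentiles, a Gamma
# percentile of baseline energy), so all detectors are invariant to channel
# amplitude scaling. Sample indices in the output are 0-based, half-open.
#
#   STE  moving RMS (3 ms) > mean + 5 SD for >= 6 ms, gaps < 10 ms merged,
#        and > 6 rectified peaks above mean + 3 SD.
#   SLL  sliding line length (80 ms) above the epoch ECDF's 97.5th pctile.
#   HIL  analytic envelope > mean + 5 SD for >= 10 ms, gaps < 10 ms merged.
#   MNI  10-ms RMS energy vs baseline: where >= 5 s/min of spectrally flat
#        (Wiener-entropy) baseline exists, threshold = 99.9999th pctile of a
#        Gamma fit to baseline RMS; otherwise an iterative 95th-ECDF-pctile
#        threshold per 1-min segment. The baseline construction makes the
#        detector agnostic to persistent high-frequency activity.

ms_to_samp <- function(ms, fs) max(1L, as.integer(round(ms / 1000 * fs)))

# runs (1-based inclusive) -> events data.frame (0-based half-open)
runs_to_events <- function(runs, site_id, detector, f_cut,
                           peak_count = NA_integer_) {
  if (is.null(runs) || nrow(runs) == 0) {
    return(data.frame(site_id = character(0), detector = character(0),
                      f_cut = numeric(0), start = integer(0),
                      end = integer(0), peak_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(site_id = site_id, detector = detector, f_cut = f_cut,
             start = as.integer(runs[, "start"] - 1L),
             end = as.integer(runs[, "end"]),
             peak_count = peak_count, stringsAsFactors = FALSE)
}

detect_ste <- function(z, fs, p) {
  rms <- moving_rms(z, ms_to_samp(p$rms_ms, fs))
  thr <- mean(rms) + p$thr_sd * stats::sd(rms)
  runs <- logical_runs(rms > thr)
  if (nrow(runs) == 0) return(list(runs = runs, peaks = integer(0)))
  runs <- runs[runs[, "end"] - runs[, "start"] + 1L >=
                 ms_to_samp(p$min_dur_ms, fs), , drop = FALSE]
  if (nrow(runs) == 0) return(list(runs = runs, peaks = integer(0)))
  runs <- merge_runs(runs, ms_to_samp(p$gap_ms, fs))
  rect <- abs(z)
  pthr <- mean(rect) + p$peak_sd * stats::sd(rect)
  n <- length(rect)
  is_peak <- c(FALSE, rect[2:(n - 1)] > rect[1:(n - 2)] &
                 rect[2:(n - 1)] >= rect[3:n], FALSE) & rect > pthr
  peak_counts <- vapply(seq_len(nrow(runs)), function(i) {
    sum(is_peak[runs[i, "start"]:runs[i, "end"]])
  }, integer(1))
  keep <- peak_counts > p$min_peaks          # "more than six peaks": strict
  list(runs = runs[keep, , drop = FALSE], peaks = peak_counts[keep])
}

detect_sll <- function(z, fs, p) {
  w <- ms_to_samp(p$window_ms, fs)
  ll <- forward_moving_sum(abs(diff(z)), w - 1L)
  thr <- stats::quantile(ll, p$pct, names = FALSE)
  runs <- logical_runs(ll > thr)
  if (nrow(runs) == 0) return(runs)
  # map window-start runs to sample spans; events last at least one window
  runs[, "end"] <- pmin(runs[, "end"] + w - 1L, length(z))
  merge_runs(runs, 1L)
}

detect_hil <- function(z, fs, p) {
  env <- Mod(analytic_signal(z))
  thr <- mean(env) + p$thr_sd * stats::sd(env)
  runs <- logical_runs(env > thr)
  if (nrow(runs) == 0) return(runs)
  runs <- merge_runs(runs, ms_to_samp(p$gap_ms, fs))
  runs[runs[, "end"] - runs[, "start"] + 1L >=
         ms_to_samp(p$min_dur_ms, fs), , drop = FALSE]
}

# Wiener entropy (spectral flatness) of one segment within band_hz.
spectral_flatness <- function(seg, fs, band_hz = c(80, 450)) {
  n <- length(seg)
  pw <- Mod(stats::fft(seg))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= band_hz[1] & freqs <= min(band_hz[2], fs / 2)
  pw <- pw[sel]
  pw <- pw[pw > 0]
  if (length(pw) < 2) return(0)
  exp(mean(log(pw))) / mean(pw)
}

# moment-fit Gamma percentile (scale-equivariant)
gamma_percentile <- function(x, pct) {
  m <- mean(x); v <- stats::var(x)
  if (v <= 0) return(m)
  shape <- m^2 / v
  rate <- m / v
  stats::qgamma(pct, shape = shape, rate = rate)
}

detect_mni <- function(z, fs, p) {
  n <- length(z)
  if (n < 60 * fs) {
    stop("MNI detector requires at least 1 min of signal for baselining")
  }
  rms <- moving_rms(z, ms_to_samp(p$rms_ms, fs))
  seg_n <- ms_to_samp(p$seg_ms, fs)
  n_seg <- floor(n / seg_n)
  flat <- vapply(seq_len(n_seg), function(s) {
    spectral_flatness(z[((s - 1) * seg_n + 1):(s * seg_n)], fs)
  }, numeric(1))
  base_seg <- which(flat > p$flatness_thr)
  base_idx <- unlist(lapply(base_seg, function(s)
    ((s - 1) * seg_n + 1):(s * seg_n)))
  minutes <- n / fs / 60
  base_s_per_min <- length(base_idx) / fs / minutes

  min_dur <- ms_to_samp(p$min_dur_ms, fs)
  gap <- ms_to_samp(p$gap_ms, fs)
  if (base_s_per_min >= p$baseline_min_s_per_min) {
    thr <- gamma_percentile(rms[base_idx], p$baseline_pct)
    runs <- logical_runs(rms > thr)
    if (nrow(runs) > 0) runs <- merge_runs(runs, gap)
  } else {
    # persistent high-frequency activity: iterative per-minute ECDF threshold
    runs_list <- list()
    n_min <- ceiling(n / (60 * fs))
    for (m in seq_len(n_min)) {
      i0 <- (m - 1) * 60 * fs + 1
      i1 <- min(m * 60 * fs, n)
      seg_rms <- rms[i0:i1]
      keep <- rep(TRUE, length(seg_rms))
      thr <- stats::quantile(seg_rms, p$fallback_pct, names = FALSE)
      for (it in 1:10) {
        keep_new <- seg_rms <= thr
        thr_new <- stats::quantile(seg_rms[keep_new], p$fallback_pct,
                                   names = FALSE)
        if (abs(thr_new - thr) < 0.01 * thr) { thr <- thr_new; break }
        thr <- thr_new
        keep <- keep_new
      }
      r <- logical_runs(seg_rms > thr)
      if (nrow(r) > 0) {
        # a detection must be an energy augmentation against the persistent
        # background, not a noise wiggle around a flat high-activity level
        med <- stats::median(seg_rms)
        peak <- vapply(seq_len(nrow(r)), function(j) {
          max(seg_rms[r[j, "start"]:r[j, "end"]])
        }, numeric(1))
        r <- r[peak >= p$fallback_min_augment * med, , drop = FALSE]
      }
      if (nrow(r) > 0) {
        r[, "start"] <- r[, "start"] + i0 - 1L
        r[, "end"] <- r[, "end"] + i0 - 1L
        runs_list[[length(runs_list) + 1L]] <- r
      }
    }
    runs <- if (length(runs_list) > 0) do.call(rbind, runs_list)
            else cbind(start = integer(0), end = integer(0))
    if (nrow(runs) > 0) runs <- merge_runs(runs, gap)
  }
  if (nrow(runs) > 0) {
    runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= min_dur, ,
                 drop = FALSE]
  }
  runs
}

#' Detect HFO events on each channel of a recording
#'
#' @param rec an \code{ieeg_recording} (>= 1 min).
#' @param detector one of \code{"STE", "SLL", "HIL", "MNI"}.
#' @param f_cut high-pass edge, Hz (80 or 150 in study-equivalent use).
#' @param config detector parameter list (see \code{\link{default_config}}
#'   \code{$hfo}); the headline thresholds (5 SD / >6 peaks over 3 SD /
#'   97.5th percentile / 5 SD / 99.9999th vs 95th percentile) are the
#'   published rules, the window lengths and merge gaps are package defaults.
#' @return data.frame of events: \code{site_id, detector, f_cut, start, end}
#'   (0-based half-open sample indices) and \code{peak_count} (STE only).
#' @export
detect_hfo <- function(rec, detector = c("HIL", "STE", "SLL", "MNI"),
                       f_cut = 80, config = default_config()$hfo) {
  stopifnot(inherits(rec, "ieeg_recording"))
  detector <- match.arg(toupper(detector[1]), c("HIL", "STE", "SLL", "MNI"))
  if (duration_s(rec) < 60) stop("HFO detection requires an epoch of >= 1 min")
  fs <- rec$fs
  out <- lapply(seq_along(rec$channel_ids), function(ci) {
    z <- fir_filter(rec$data[ci, ], fs, f_cut)$x
    sid <- rec$channel_ids[ci]
    switch(detector,
      STE = {
        r <- detect_ste(z, fs, config$ste)
        runs_to_events(r$runs, sid, "STE", f_cut,
                       if (length(r$peaks)) r$peaks else NA_integer_)
      },
      SLL = runs_to_events(detect_sll(z, fs, config$sll), sid, "SLL", f_cut),
      HIL = runs_to_events(detect_hil(z, fs, config$hil), sid, "HIL", f_cut),
      MNI = runs_to_events(detect_mni(z, fs, config$mni), sid, "MNI", f_cut))
  })
  do.call(rbind, out)
}

#' HFO occurrence rate
#'
#' @param events events data.frame from \code{\link{detect_hfo}} (possibly
#'   zero rows).
#' @param epoch_duration_min epoch length in minutes (> 0).
#' @return data.frame \code{(site_id, detector, f_cut, n_events, rate,
#'   epoch_duration)}; rate in events/minute. Channels with no events must be
#'   supplied via \code{site_ids} to appear with rate 0.
#' @param site_ids optional character vector of all channels that were
#'   scanned (so empty channels get rate 0).
#' @export
compute_rate <- function(events, epoch_duration_min, site_ids = NULL) {
  if (epoch_duration_min <= 0) stop("epoch duration must be positive")
  ids <- if (!is.null(site_ids)) site_ids else unique(events$site_id)
  counts <- vapply(ids, function(s) sum(events$site_id == s), integer(1))
  data.frame(site_id = ids,
             detector = if (nrow(events) > 0) events$detector[1] else NA_character_,
             f_cut = if (nrow(events) > 0) events$f_cut[1] else NA_real_,
             n_events = counts,
             rate = counts / epoch_duration_min,
             epoch_duration = epoch_duration_min,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read an HFO events table (TSV, seconds)
#'
#' @param events events data.frame; \code{fs} converts sample indices to
#'   seconds on disk.
#' @param path TSV path.
#' @param fs sampling rate used for the conversion.
#' @export
write_events <- function(events, path, fs) {
  out <- data.frame(site_id = events$site_id, detector = events$detector,
                    start_s = events$start / fs, end_s = events$end / fs)
  tsv_write(out, path)
}
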