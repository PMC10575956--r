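# Slow-wave-sleep epoch validation and onset-time statistics.

#' Validate a candidate slow-wave-sleep epoch
#'
#' Operationalizes the "low-frequency (<2 Hz) activity for at least 20% of
#' the time during each 30-s epoch" rule as a per-second delta-dominance
#' criterion: within every 1-s bin and channel, the 0.5-2 Hz band power must
#' be at least 50% of the 0.5-40 Hz band power (Welch periodogram, 1-s
#' windows, no overlap). The per-window fraction of delta-dominant bins is
#' the median across the supplied nonepileptic channels; the epoch passes iff
#' every 30-s window reaches the 20% fraction (boundary inclusive). The
#' power-ratio form makes the rule invariant to channel-wise amplitude
#' scaling.
#'
#' @param rec an \code{ieeg_recording}.
#' @param nonepileptic_channels channel ids (or indices) used for scoring.
#' @param epoch_min required epoch length, minutes (default 20).
#' @param window_s scoring window, s.
#' @param bin_s dominance bin, s.
#' @param delta_band,broad_band frequency bands, Hz.
#' @param dominance required delta share of broad-band power within a bin.
#' @param min_fraction required fraction of delta-dominant bins per window.
#' @return list of class \code{sws_validation}: \code{window_fraction}
#'   (per 30-s window), \code{pass}, \code{onset_hours}.
#' @export
validate_sws_epoch <- function(rec, nonepileptic_channels = rec$channel_ids,
                               epoch_min = 20, window_s = 30, bin_s = 1,
                               delta_band = c(0.5, 2), broad_band = c(0.5, 40),
                               dominance = 0.5, min_fraction = 0.20) {
  stopifnot(inherits(rec, "ieeg_recording"))
  if (length(nonepileptic_channels) < 1) {
    stop("at least one nonepileptic channel is required")
  }
  need_s <- epoch_min * 60
  if (duration_s(rec) < need_s) {
    stop("epoch shorter than required: need ", epoch_min,
         " min (", need_s, " s), got ", duration_s(rec), " s")
  }
  fs <- rec$fs
  bin_n <- round(bin_s * fs)
  n_bins <- floor(need_s / bin_s)
  bins_per_window <- round(window_s / bin_s)
  n_windows <- floor(n_bins / bins_per_window)

  freqs <- (seq_len(bin_n) - 1) * (1 / bin_s)
  in_band <- function(band) freqs >= band[1] & freqs <= band[2] & freqs > 0
  sel_delta <- in_band(delta_band)
  sel_broad <- in_band(broad_band)

  dom <- vapply(nonepileptic_channels, function(ch) {
    x <- channel_vector(rec, ch)
    vapply(seq_len(n_bins), function(b) {
      seg <- x[((b - 1) * bin_n + 1):(b * bin_n)]
      p <- Mod(stats::fft(seg - mean(seg)))^2
      pd <- sum(p[sel_delta])
      pb <- sum(p[sel_broad])
      if (pb <= 0) return(FALSE)
      pd >= dominance * pb
    }, logical(1))
  }, logical(n_bins))

  frac_by_chan <- matrix(0, nrow = n_windows, ncol = ncol(dom))
  for (w in seq_len(n_windows)) {
    rows <- ((w - 1) * bins_per_window + 1):(w * bins_per_window)
    frac_by_chan[w, ] <- colMeans(dom[rows, , drop = FALSE])
  }
  window_fraction <- apply(frac_by_chan, 1, stats::median)
  structure(list(window_fraction = window_fraction,
                 pass = all(window_fraction >= min_fraction),
                 onset_hours = rec$epoch_start),
            class = "sws_validation")
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of angles deviates from the uniform circular
#' distribution: \eqn{z = n \bar R^2} with \eqn{\bar R} the mean resultant
#' length, and p-value from Zar's approximation
#' \eqn{p = \exp(\sqrt{1 + 4n + 4(n^2 - (n\bar R)^2)} - (1 + 2n))}.
#' Used on slow-wave-sleep epoch onset clock times mapped to angles by
#' \code{2 * pi * hour / 24}.
#'
#' @param angles radians, n >= 2.
#' @return list \code{(zvalue, pvalue, rbar, n)}.
#' @export
rayleigh_test <- function(angles) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 2) stop("rayleigh_test needs at least 2 finite angles")
  rbar <- Mod(mean(exp(1i * angles)))
  z <- n * rbar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * rbar)^2)) - (1 + 2 * n))
  list(zvalue = z, pvalue = min(1, p), rbar = rbar, n = n)
}

#' @rdname rayleigh_test
#' @param hours clock times as decimal hours in [0, 24).
#' @export
hours_to_angle <- function(hours) 2 * pi * hours / 24

#' Spearman correlation of epoch onset time with age
#'
#' Tie-corrected rank correlation with p-value from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom.
#'
#' @param onsets epoch onset clock hours.
#' @param ages subject ages, years.
#' @return list \code{(rho, pvalue, n, undefined)}; \code{undefined} is TRUE
#'   when either vector is constant (rho has no meaning).
#' @export
onset_age_correlation <- function(onsets, ages) {
  if (length(onsets) != length(ages)) stop("onsets and ages differ in length")
  ok <- is.finite(onsets) & is.finite(ages)
  onsets <- onsets[ok]; ages <- ages[ok]
  n <- length(onsets)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(onsets) == 0 || stats::sd(ages) == 0) {
    return(list(rho = NA_real_, pvalue = NA_real_, n = n, undefined = TRUE))
  }
  rho <- stats::cor(rank(onsets), rank(ages))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, pvalue = p, n = n, undefined = FALSE)
}
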