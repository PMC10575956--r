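# Phase-amplitude coupling: the modulation index MI_{>=f Hz & s Hz} between
# the amplitude of high-pass-filtered (>= f Hz) activity and the phase of a
# slow-wave band (s Hz). MI here is the amplitude-normalized mean vector
# length, MI = |sum_t A(t) e^{i phi(t)}| / sum_t A(t), which is dimensionless,
# lies in [0, 1], and is invariant to amplitude scaling of the channel. The
# raw (unnormalized, signal-units) variant is available via `normalize = FALSE`.

#' Instantaneous slow-wave phase
#'
#' Zero-phase band-pass (Hamming FIR, forward-backward) followed by the
#' analytic-signal angle. Phase 0 falls at the positive peak of the
#' band-passed waveform (cosine convention).
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param s_band phase band (lo, hi), Hz.
#' @return list \code{(phase, edge)}: phase in (-pi, pi] and the number of
#'   filter-edge samples to exclude at each end.
#' @export
extract_phase <- function(x, fs, s_band) {
  flt <- fir_filter(x, fs, s_band[1], s_band[2])
  list(phase = Arg(analytic_signal(flt$x)), edge = flt$edge)
}

#' High-frequency amplitude envelope
#'
#' Zero-phase high-pass at \code{f_cut} (with anti-alias upper limit
#' \code{min(upper_hz, 0.9 * fs/2)}), then the analytic-signal magnitude.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param f_cut high-pass edge, Hz (80 or 150 in study-equivalent use).
#' @param upper_hz upper band limit before the anti-alias cap.
#' @return list \code{(envelope, edge)}; envelope is nonnegative.
#' @export
extract_envelope <- function(x, fs, f_cut, upper_hz = 330) {
  hi <- min(upper_hz, 0.9 * fs / 2)
  flt <- if (hi <= f_cut) fir_filter(x, fs, f_cut)
         else fir_filter(x, fs, f_cut, hi)
  list(envelope = Mod(analytic_signal(flt$x)), edge = flt$edge)
}

#' Modulation index from phase and amplitude series
#'
#' The core statistic: \code{MI = |sum(A * exp(1i*phi))| / sum(A)} when
#' normalized, or \code{|mean(A * exp(1i*phi))|} (signal units) when not.
#'
#' @param phase radians.
#' @param amplitude nonnegative envelope, same length.
#' @param normalize divide by \code{sum(amplitude)} (default TRUE).
#' @return scalar MI; \code{NA} with a warning if the envelope is all zero.
#' @export
mi_from_phase_amp <- function(phase, amplitude, normalize = TRUE) {
  stopifnot(length(phase) == length(amplitude))
  s <- sum(amplitude)
  if (s <= 0) {
    warning("all-zero envelope: MI undefined")
    return(NA_real_)
  }
  v <- Mod(sum(amplitude * exp(1i * phase)))
  if (normalize) v / s else v / length(phase)
}

#' Modulation index of a recording
#'
#' One MI value per channel over the whole epoch (no sub-windowing), with
#' filter-edge samples (one filter length per side, the larger of the two
#' filters) excluded. MI is only reported when the retained segment holds at
#' least \code{min_cycles} slow-wave cycles at the band's lower edge.
#'
#' @param rec an \code{ieeg_recording}.
#' @param f_cut amplitude high-pass edge, Hz.
#' @param s_band phase band (lo, hi), Hz.
#' @param normalize amplitude-normalized MI (default) or raw mean vector
#'   length in signal units.
#' @param upper_hz upper limit of the amplitude band.
#' @param min_cycles minimum slow-wave cycles required (default 10).
#' @return data.frame with columns \code{site_id, f_cut, s_lo, s_hi, mi,
#'   n_samples}.
#' @export
compute_mi <- function(rec, f_cut = 80, s_band = c(0.5, 1), normalize = TRUE,
                       upper_hz = 330, min_cycles = 10) {
  stopifnot(inherits(rec, "ieeg_recording"))
  fs <- rec$fs
  out <- lapply(seq_along(rec$channel_ids), function(ci) {
    x <- rec$data[ci, ]
    ph <- extract_phase(x, fs, s_band)
    en <- extract_envelope(x, fs, f_cut, upper_hz)
    edge <- max(ph$edge, en$edge)
    keep <- (edge + 1):(length(x) - edge)
    if (length(keep) < min_cycles * fs / s_band[1]) {
      stop("retained segment holds fewer than ", min_cycles,
           " slow-wave cycles at ", s_band[1], " Hz")
    }
    mi <- mi_from_phase_amp(ph$phase[keep], en$envelope[keep],
                            normalize = normalize)
    data.frame(site_id = rec$channel_ids[ci], f_cut = f_cut,
               s_lo = s_band[1], s_hi = s_band[2], mi = mi,
               n_samples = length(keep), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' MI across the slow-wave band grid and its spectral slope
#'
#' Computes MI for each band of the slow-wave grid (default: the eight
#' 1-Hz-wide bands 0.5-1 ... 7-8 Hz) and the per-channel ordinary
#' least-squares slope of MI against band centre frequency (units /Hz). A
#' negative slope means coupling is stronger to lower-frequency slow waves.
#'
#' @param rec an \code{ieeg_recording}.
#' @param f_cut amplitude high-pass edge, Hz.
#' @param s_grid list of (lo, hi) bands; at least 2.
#' @param ... passed to \code{\link{compute_mi}}.
#' @return list: \code{mi} (long data.frame: site_id, band centre, mi) and
#'   \code{slope} (data.frame: site_id, slope_per_hz).
#' @export
mi_band_profile <- function(rec, f_cut = 80,
                            s_grid = default_config()$bands$s_grid, ...) {
  if (length(s_grid) < 2) stop("need at least 2 slow-wave bands")
  rows <- lapply(s_grid, function(b) {
    r <- compute_mi(rec, f_cut = f_cut, s_band = b, ...)
    r$center <- mean(b)
    r
  })
  mi_tab <- do.call(rbind, rows)
  list(mi = mi_tab, slope = band_profile_slope(mi_tab))
}

#' Ordinary least-squares slope of MI against band centre frequency
#'
#' @param mi_tab long data.frame with columns \code{site_id, center, mi}.
#' @return data.frame \code{(site_id, slope_per_hz)}.
#' @export
band_profile_slope <- function(mi_tab) {
  if (length(unique(mi_tab$center)) < 2) stop("need at least 2 bands")
  slope <- do.call(rbind, lapply(split(mi_tab, mi_tab$site_id), function(d) {
    fit <- stats::lm(mi ~ center, data = d)
    data.frame(site_id = d$site_id[1],
               slope_per_hz = unname(stats::coef(fit)[2]),
               stringsAsFactors = FALSE)
  }))
  rownames(slope) <- NULL
  slope
}

#' Per-lobe mean of the MI band-profile slope
#'
#' @param slopes data.frame from \code{mi_band_profile} (site_id,
#'   slope_per_hz) for many sites.
#' @param sites sites table mapping site_id to lobe.
#' @return data.frame (lobe, mean_slope_per_hz, n_sites).
#' @export
lobe_band_slope <- function(slopes, sites) {
  lobe <- sites$lobe[match(slopes$site_id, sites$site_id)]
  agg <- stats::aggregate(slopes$slope_per_hz, by = list(lobe = lobe),
                          FUN = mean)
  n <- stats::aggregate(slopes$slope_per_hz, by = list(lobe = lobe),
                        FUN = length)
  data.frame(lobe = agg$lobe, mean_slope_per_hz = agg$x, n_sites = n$x)
}
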