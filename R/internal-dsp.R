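# Shared signal-processing primitives. All filters are zero-phase linear-phase
# FIR (Hamming window via signal::fir1), applied forward-backward; edge samples
# (one filter length each side) are reported so callers can exclude them.

# Analytic signal via frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Full linear convolution via FFT (lengths la + lb - 1).
conv_full <- function(a, b) {
  la <- length(a)
  lb <- length(b)
  n <- la + lb - 1
  nfft <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(a, numeric(nfft - la))) *
                       stats::fft(c(b, numeric(nfft - lb))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# FIR order from the 25%-of-band-edge transition-width rule (Hamming: ~3.3/tw
# normalized). Capped so short test signals keep a usable interior.
fir_order <- function(fs, edge_hz, n_samples, trans_frac = 0.25) {
  tw <- trans_frac * edge_hz
  ord <- ceiling(3.3 * fs / tw)
  cap <- max(32L, floor(n_samples / 6))
  ord <- min(ord, cap)
  if (ord %% 2 == 1) ord <- ord + 1L  # even order -> odd, type-I taps
  as.integer(ord)
}

# Zero-phase filter: forward-backward application of a symmetric FIR, done as a
# single convolution with conv(b, rev(b)) and centre-aligned extraction.
zero_phase_filter <- function(x, b) {
  n <- length(x)
  nb <- length(b)
  h <- conv_full(b, rev(b))        # length 2*nb - 1, zero-phase at lag nb - 1
  y <- conv_full(h, x)             # length n + 2*nb - 2
  y[nb:(nb + n - 1)]
}

# Band-pass / high-pass with edge bookkeeping. `hi = NULL` means high-pass.
# Returns list(x = filtered series, edge = samples to discard per side).
fir_filter <- function(x, fs, lo, hi = NULL, trans_frac = 0.25) {
  nyq <- fs / 2
  if (lo <= 0 || lo >= nyq) stop("low band edge must lie in (0, fs/2)")
  if (!is.null(hi) && (hi <= lo || hi > nyq)) {
    stop("band edges must satisfy 0 < lo < hi <= fs/2")
  }
  ord <- fir_order(fs, lo, length(x), trans_frac)
  if (ord + 1 >= length(x)) {
    stop("signal too short for filter design at this band (need > ",
         ord + 1, " samples)")
  }
  b <- if (is.null(hi)) {
    signal::fir1(ord, lo / nyq, type = "high")
  } else if (hi >= 0.999 * nyq) {
    signal::fir1(ord, lo / nyq, type = "high")
  } else {
    signal::fir1(ord, c(lo, hi) / nyq, type = "pass")
  }
  list(x = zero_phase_filter(x, as.numeric(b)), edge = ord + 1L)
}

# Centered moving mean (window w samples) via cumulative sums; edges use the
# available samples (shrinking window).
moving_mean <- function(x, w) {
  n <- length(x)
  w <- max(1L, as.integer(w))
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  cs <- c(0, cumsum(x))
  i0 <- pmax(seq_len(n) - half_lo, 1L)
  i1 <- pmin(seq_len(n) + half_hi, n)
  (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
}

moving_rms <- function(x, w) sqrt(moving_mean(x^2, w))

# Moving sum over a forward-looking window of length w (for line length):
# y[i] = sum(x[i:(i+w-1)]), defined for i in 1..(n-w+1).
forward_moving_sum <- function(x, w) {
  n <- length(x)
  if (w > n) stop("window longer than series")
  cs <- c(0, cumsum(x))
  cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
}

# Maximal runs of TRUE in a logical vector -> matrix(start, end) 1-based
# inclusive; zero rows when no run.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Merge intervals (1-based inclusive, sorted by start) whose gap is < max_gap
# samples.
merge_runs <- function(runs, max_gap) {
  if (nrow(runs) <= 1) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    gap <- runs[i, "start"] - out[nrow(out), "end"] - 1L
    if (gap < max_gap) {
      out[nrow(out), "end"] <- max(out[nrow(out), "end"], runs[i, "end"])
    } else {
      out <- rbind(out, runs[i, , drop = FALSE])
    }
  }
  out
}

# Counter-based substream: expand one global seed into independent per-unit
# seeds (SplitMix-style mixing, kept below 2^31).
substream_seed <- function(seed, index) {
  x <- (as.double(seed) * 2654435761 + as.double(index) * 40503 + 12345) %% 2147483647
  as.integer(x)
}
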