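test_that("phase extraction follows the cosine convention", {
  fs <- 1000
  tt <- (0:(120 * fs - 1)) / fs
  x <- cos(2 * pi * 0.75 * tt)
  ph <- extract_phase(x, fs, c(0.5, 1))
  keep <- (ph$edge + 1):(length(x) - ph$edge)
  # phase 0 at each cosine peak
  peaks <- which(abs((tt * 0.75) %% 1) < 1e-9)
  peaks <- peaks[peaks > ph$edge & peaks < length(x) - ph$edge]
  expect_gt(length(peaks), 10)
  expect_lt(max(abs(ph$phase[peaks])), 0.05)

  # sign flip shifts the phase by pi at former peaks
  ph2 <- extract_phase(-x, fs, c(0.5, 1))
  expect_lt(max(abs(abs(ph2$phase[peaks]) - pi)), 0.05)

  # unwrapped phase slope = 2*pi*0.75 rad/s within 1%
  dphi <- diff(ph$phase[keep])
  dphi[dphi < -pi] <- dphi[dphi < -pi] + 2 * pi
  slope <- mean(dphi) * fs
  expect_equal(slope, 2 * pi * 0.75, tolerance = 0.01)
})

test_that("envelope extraction recovers a known modulator and is linear", {
  fs <- 1000
  tt <- (0:(60 * fs - 1)) / fs
  mod <- (1 + cos(2 * pi * 0.75 * tt)) / 2
  x <- mod * cos(2 * pi * 120 * tt)
  en <- extract_envelope(x, fs, 80)
  keep <- (en$edge + 1):(length(x) - en$edge)
  expect_gt(cor(en$envelope[keep], mod[keep]), 0.99)
  expect_true(all(en$envelope >= 0))

  en2 <- extract_envelope(2 * x, fs, 80)
  expect_equal(en2$envelope, 2 * en$envelope, tolerance = 1e-9)

  expect_equal(extract_envelope(numeric(60000), fs, 80)$envelope,
               numeric(60000))
})

test_that("modulation index hits its closed forms", {
  phi <- seq(-pi, pi, length.out = 40001)[-1]
  # A = 1 + cos(phi): analytic MI = 1/2
  expect_equal(mi_from_phase_amp(phi, 1 + cos(phi)), 0.5, tolerance = 1e-3)
  # constant amplitude, uniform phase: MI ~ 0
  expect_lt(mi_from_phase_amp(phi, rep(1, length(phi))), 1e-3)
  # perfectly phase-locked bursts: MI -> 1
  expect_gt(mi_from_phase_amp(phi, as.numeric(abs(phi) < 0.01)), 0.999)
  # all-zero envelope is flagged undefined
  expect_warning(out <- mi_from_phase_amp(phi, numeric(length(phi))),
                 "undefined")
  expect_true(is.na(out))
})

test_that("MI is invariant to channel amplitude scaling", {
  sp <- signal_spec(duration = 60, coupling_depth = 0.8,
                    hfo_burst_rate = Inf, noise_sd = 3, seed = 12)
  s <- simulate_signal(sp)
  rec2 <- s$recording
  rec2$data <- rec2$data * 41.7
  m1 <- compute_mi(s$recording)$mi
  m2 <- compute_mi(rec2)$mi
  expect_equal(m1, m2, tolerance = 1e-10)
  # while the raw (unnormalized) variant scales with the signal
  r1 <- compute_mi(s$recording, normalize = FALSE)$mi
  r2 <- compute_mi(rec2, normalize = FALSE)$mi
  expect_equal(r2 / r1, 41.7, tolerance = 1e-6)
})

test_that("phase-randomized surrogates destroy the measured coupling", {
  sp <- signal_spec(duration = 60, coupling_depth = 1, seed = 13)
  s <- simulate_signal(sp)
  x <- s$recording$data[1, ]
  fs <- 1000
  ph <- extract_phase(x, fs, c(0.5, 1))
  en <- extract_envelope(x, fs, 80)
  edge <- max(ph$edge, en$edge)
  keep <- (edge + 1):(length(x) - edge)
  phi <- ph$phase[keep]; env <- en$envelope[keep]
  mi_true <- mi_from_phase_amp(phi, env)
  set.seed(14)
  n <- length(env)
  shifts <- sample(2000:(n - 2000), 100)   # >= 1 slow cycle
  mi_surr <- vapply(shifts, function(s0) {
    mi_from_phase_amp(phi, c(env[(s0 + 1):n], env[1:s0]))
  }, numeric(1))
  expect_lte(mean(mi_surr), 0.03)
  expect_gt(mi_true, mean(mi_surr))
})

test_that("band-profile slope equals exact OLS on constructed MI values", {
  centers <- c(0.75, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5)
  tab <- data.frame(site_id = "e1", center = centers,
                    mi = 0.2 - 0.02 * centers)
  sl <- band_profile_slope(tab)
  expect_equal(sl$slope_per_hz, -0.02, tolerance = 1e-12)
  flat <- data.frame(site_id = "e1", center = centers, mi = 0.1)
  expect_equal(band_profile_slope(flat)$slope_per_hz, 0, tolerance = 1e-12)
  expect_error(band_profile_slope(tab[1, ]), "2 bands")
})

test_that("mi_band_profile sees stronger coupling at the generating band", {
  sp <- signal_spec(duration = 120, slow_band = c(0.5, 1),
                    coupling_depth = 1, hfo_burst_rate = Inf,
                    noise_sd = 2, seed = 15)
  s <- simulate_signal(sp)
  prof <- mi_band_profile(s$recording, f_cut = 80,
                          s_grid = list(c(0.5, 1), c(3, 4), c(7, 8)))
  mi <- prof$mi$mi
  expect_gt(mi[1], mi[2])
  expect_gt(mi[1], mi[3])
  expect_lt(prof$slope$slope_per_hz, 0)
})

test_that("too-short segments for the slow band are rejected", {
  rec <- recording(matrix(rnorm(3000), nrow = 1), fs = 1000)
  expect_error(compute_mi(rec, s_band = c(0.5, 1)), "cycles")
})
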