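test_that("signal generator is deterministic and validates its spec", {
  sp <- signal_spec(duration = 10, seed = 7)
  a <- simulate_signal(sp)
  b <- simulate_signal(sp)
  expect_identical(a$recording$data, b$recording$data)
  expect_equal(n_samples(a$recording), 10 * 1000)
  expect_error(signal_spec(hfo_freq = 600), "fs/2")
  expect_error(signal_spec(coupling_depth = 1.2), "\\[0, 1\\]")
  expect_error(signal_spec(hfo_burst_rate = -1), ">= 0")
})

test_that("kappa=0 leaves the HFO envelope independent of slow phase", {
  sp <- signal_spec(duration = 60, coupling_depth = 0, hfo_burst_rate = Inf,
                    noise_sd = 2, seed = 2)
  s <- simulate_signal(sp)
  env <- extract_envelope(s$recording$data[1, ], 1000, 80)$envelope
  phi <- s$truth$slow_phase
  keep <- 10000:50000
  # circular-linear correlation of envelope with phase
  r1 <- cor(env[keep], cos(phi[keep]))
  r2 <- cor(env[keep], sin(phi[keep]))
  expect_lt(sqrt(r1^2 + r2^2), 0.05)
})

test_that("kappa=1 puts the envelope peak at the preferred phase", {
  sp <- signal_spec(duration = 60, coupling_depth = 1, hfo_burst_rate = Inf,
                    preferred_phase = 0, noise_sd = 1, seed = 3)
  s <- simulate_signal(sp)
  env <- extract_envelope(s$recording$data[1, ], 1000, 80)$envelope
  phi <- s$truth$slow_phase
  keep <- 10000:50000
  # oracle: per-cycle argmax of the analytic envelope
  wraps <- which(diff(phi[keep]) < -pi)
  ok <- 0; total <- 0
  for (i in seq_len(length(wraps) - 1)) {
    cyc <- keep[(wraps[i] + 1):wraps[i + 1]]
    if (length(cyc) < 100) next
    total <- total + 1
    ph_at_max <- phi[cyc[which.max(env[cyc])]]
    if (abs(ph_at_max) <= pi / 8) ok <- ok + 1
  }
  expect_gt(total, 20)
  expect_gte(ok / total, 0.95)
})

test_that("burst gate ground truth matches the generated bursts", {
  sp <- signal_spec(duration = 30, hfo_burst_rate = 20, coupling_depth = 0,
                    noise_sd = 0, slow_amp = 0, hfo_amp = 10, seed = 5)
  s <- simulate_signal(sp)
  tr <- s$truth$burst_intervals
  expect_true(all(tr[, "start"] < tr[, "end"]))
  expect_true(all(tr[, "end"] <= n_samples(s$recording)))
  # energy inside truth intervals, silence outside
  x <- s$recording$data[1, ]
  inside <- unlist(lapply(seq_len(nrow(tr)), function(i)
    (tr[i, "start"] + 1):tr[i, "end"]))
  expect_gt(stats::sd(x[inside]), 1)
  expect_equal(stats::sd(x[-inside]), 0)
})

test_that("cohort curves evaluate exactly with zero noise", {
  curves <- mi_only_curves()
  curves$noise_sd <- 0
  cs <- cohort_spec(n_subjects = 2, age_range = c(9, 9),
                    sites_per_lobe = c(frontal = 2, temporal = 2,
                                       parietal = 2, occipital = 2),
                    n_soz = 0, curves = curves, soz_shift = c(mi80_0.5_1 = 0),
                    seed = 4)
  co <- simulate_cohort(cs)
  occ <- co$sites$lobe == "occipital"
  # 0.05 + 0.047 * sqrt(9) = 0.191
  expect_equal(unique(co$biomarkers$mi80_0.5_1[occ]), 0.191)
})

test_that("cohort respects age bounds, SOZ exchangeability and rate clipping", {
  cs <- cohort_spec(n_subjects = 114, curves = mi_only_curves(),
                    soz_shift = c(mi80_0.5_1 = 0), seed = 6)
  co <- simulate_cohort(cs)
  ages <- co$subjects$age
  expect_true(all(ages >= 1.0 & ages <= 41.5))
  # zero SOZ shift: SOZ and nonepileptic values exchangeable within lobe
  for (lb in unique(co$sites$lobe)) {
    sel <- co$sites$lobe == lb
    v <- co$biomarkers$mi80_0.5_1[sel]
    g <- co$sites$is_soz[sel]
    if (sum(g) > 30) {
      expect_lt(abs(mean(v[g]) - mean(v[!g])), 4 * sd(v) / sqrt(sum(g)))
    }
  }
  # negative rates are clipped with a warning
  rc <- data.frame(biomarker = "rate_x", lobe = "frontal", intercept = 0.5,
                   slope = 0, noise_sd = 2)
  cs2 <- cohort_spec(n_subjects = 20,
                     sites_per_lobe = c(frontal = 10), n_soz = 0,
                     curves = rc, soz_shift = c(rate_x = 0), seed = 7)
  expect_warning(co2 <- simulate_cohort(cs2), "clipped")
  expect_true(all(co2$biomarkers$rate_x >= 0))
})

test_that("icosphere has the exact vertex/face counts and a full partition", {
  m0 <- make_sphere_mesh(0)
  expect_equal(nrow(m0$vertices), 12)
  expect_equal(nrow(m0$faces), 20)
  m3 <- make_sphere_mesh(3)
  expect_equal(nrow(m3$vertices), 10 * 4^3 + 2)
  # every vertex in exactly one patch
  memb <- sort(unlist(m3$patches))
  expect_equal(as.integer(memb), seq_len(642))
  # every vertex has exactly one lobe
  expect_true(all(m3$lobe %in% c("frontal", "temporal", "parietal",
                                 "occipital")))
  # radius 100 mm
  expect_equal(unname(sqrt(rowSums(m3$vertices^2))), rep(100, 642))
  expect_error(make_sphere_mesh(-1), "n_subdiv")
})

test_that("mesh patches are connected and deterministic", {
  m <- make_sphere_mesh(2)
  edges <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  adj <- split(edges[, 2], edges[, 1])
  for (p in m$patches) {
    inp <- rep(FALSE, nrow(m$vertices)); inp[p] <- TRUE
    seen <- rep(FALSE, nrow(m$vertices))
    queue <- p[1]; seen[p[1]] <- TRUE
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      nb <- adj[[as.character(u)]]
      nb <- nb[inp[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    expect_true(all(seen[p]))
  }
  m2 <- make_sphere_mesh(2)
  expect_identical(m$patches, m2$patches)
})
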