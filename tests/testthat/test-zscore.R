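# small synthetic reference cohorts built directly as tables
ref_cohort <- function(n = 60, age = 5, value_fun = function(n) rnorm(n, 0.2, 0.05),
                       seed = 40) {
  set.seed(seed)
  sites <- data.frame(
    site_id = sprintf("r%03d", seq_len(n)),
    subject_id = sprintf("rs%03d", seq_len(n)),   # one site per subject
    x = runif(n, -50, 50), y = runif(n, -50, 50), z = runif(n, -50, 50),
    lobe = "occipital", hemisphere = "left",
    is_soz = FALSE, is_spike_zone = FALSE, is_lesion = FALSE,
    stringsAsFactors = FALSE)
  subjects <- data.frame(subject_id = sites$subject_id,
                         age = rep(age, n), sex = "female", n_asm = 0L,
                         has_mri_lesion = FALSE, soz_lobes = "",
                         sampled_hemisphere = "left",
                         stringsAsFactors = FALSE)
  list(sites = sites, subjects = subjects, values = value_fun(n))
}

test_that("nearest-30 selection equals a brute-force full sort", {
  rc <- ref_cohort(n = 40)
  q <- c(0, 0, 0)
  ref <- normative_reference(q, 5, "query", rc$sites, rc$values, rc$subjects)
  d <- sqrt(rc$sites$x^2 + rc$sites$y^2 + rc$sites$z^2)
  brute <- rc$sites$site_id[order(d, rc$sites$site_id)][1:30]
  expect_setequal(ref$site_ids, brute)
  expect_equal(ref$mean, mean(rc$values[match(brute, rc$sites$site_id)]))
  expect_equal(ref$sd, sd(rc$values[match(brute, rc$sites$site_id)]))
})

test_that("the forward age window [n, n+3.9] excludes older donors", {
  rc <- ref_cohort(n = 60)
  rc$subjects$age <- c(rep(4, 30), rep(7.0, 30))   # half in, half out
  ref <- normative_reference(c(0, 0, 0), 3.0, "query", rc$sites, rc$values,
                             rc$subjects)
  donors <- rc$subjects$age[match(
    rc$sites$subject_id[match(ref$site_ids, rc$sites$site_id)],
    rc$subjects$subject_id)]
  expect_true(all(donors <= 6.9))
  # and the query subject's own sites never enter
  rc2 <- ref_cohort(n = 60)
  rc2$sites$subject_id[1] <- "query"
  ref2 <- normative_reference(c(0, 0, 0), 5, "query", rc2$sites, rc2$values,
                              rc2$subjects)
  expect_false(rc2$sites$site_id[1] %in% ref2$site_ids)
})

test_that("too few eligible sites errors unless widening is allowed", {
  rc <- ref_cohort(n = 20)
  expect_error(normative_reference(c(0, 0, 0), 5, "q", rc$sites, rc$values,
                                   rc$subjects), "eligible")
  rc2 <- ref_cohort(n = 60)
  rc2$subjects$age <- c(rep(5, 20), rep(20, 40))   # only 20 in [5, 8.9]
  ref <- normative_reference(c(0, 0, 0), 5, "q", rc2$sites, rc2$values,
                             rc2$subjects, widen_if_short = TRUE)
  expect_true(ref$widened)
  expect_length(ref$site_ids, 30)
})

test_that("z-score arithmetic and degenerate-SD flagging", {
  rc <- ref_cohort(n = 35, value_fun = function(n) rep(0.2, n))
  ref <- normative_reference(c(0, 0, 0), 5, "q", rc$sites, rc$values,
                             rc$subjects)
  expect_equal(ref$mean, 0.2)
  expect_equal(ref$sd, 0)
  z <- zscore(0.3, ref)
  expect_true(z$undefined)
  expect_true(is.na(z$z))

  z2 <- zscore(0.3, list(mean = 0.2, sd = 0.05, site_ids = letters[1:30]))
  expect_equal(z2$z, 2.0)
  z3 <- zscore(0.2, list(mean = 0.2, sd = 0.05, site_ids = letters[1:30]))
  expect_equal(z3$z, 0)
})

test_that("z is invariant under a common affine transform of all values", {
  rc <- ref_cohort(n = 60)
  ref1 <- normative_reference(c(0, 0, 0), 5, "q", rc$sites, rc$values,
                              rc$subjects)
  z1 <- zscore(0.31, ref1)$z
  vals2 <- 3.7 * rc$values + 11
  ref2 <- normative_reference(c(0, 0, 0), 5, "q", rc$sites, vals2,
                              rc$subjects)
  z2 <- zscore(3.7 * 0.31 + 11, ref2)$z
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("zscore_table separates shifted SOZ sites from nonepileptic ones", {
  cs <- cohort_spec(n_subjects = 30, age_range = c(5, 10),
                    sites_per_lobe = c(frontal = 4, temporal = 4,
                                       parietal = 4, occipital = 4),
                    n_soz = 4, curves = flat_mi_curves(),
                    soz_shift = c(mi80_0.5_1 = 0.15), seed = 41)
  co <- simulate_cohort(cs)
  zt <- zscore_table(co$biomarkers, co$sites, co$subjects,
                     widen_if_short = TRUE)
  soz <- co$sites$is_soz[match(zt$site_id, co$sites$site_id)]
  expect_gt(mean(zt$z[soz], na.rm = TRUE), 1.5)
  expect_lt(abs(mean(zt$z[!soz], na.rm = TRUE)), 0.3)
})
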