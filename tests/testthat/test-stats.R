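test_that("the zero-variance constraint reduces the mixed model to OLS", {
  set.seed(50)
  d <- data.frame(subject_id = rep(sprintf("s%02d", 1:20), each = 10),
                  x = rnorm(200))
  d$y <- 1 + 0.5 * d$x + rnorm(200, 0, 0.3)
  fm <- fit_mixed(d, "y", "x", constrain_zero_ranef = TRUE)
  X <- cbind(1, d$x)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)     # normal-equations oracle
  expect_equal(fm$coefficients$estimate, as.numeric(beta), tolerance = 1e-6)
  expect_equal(fm$ranef_var, 0)
  # the unconstrained fit on no-between-variance data lands close to OLS
  fm2 <- fit_mixed(d, "y", "x")
  expect_equal(fm2$coefficients$estimate, as.numeric(beta), tolerance = 0.02)
})

test_that("mixed model recovers a known fixed slope with random intercepts", {
  set.seed(51)
  n_pat <- 60; n_site <- 15
  d <- data.frame(subject_id = rep(sprintf("s%02d", 1:n_pat), each = n_site))
  u <- rnorm(n_pat, 0, 0.4)
  d$x <- rnorm(n_pat * n_site)
  d$y <- 2 + 0.05 * d$x + u[rep(1:n_pat, each = n_site)] +
    rnorm(n_pat * n_site, 0, 0.2)
  fm <- fit_mixed(d, "y", "x")
  cf <- fm$coefficients[fm$coefficients$term == "x", ]
  expect_lt(cf$ci_lo, 0.05)
  expect_gt(cf$ci_hi, 0.05)
  expect_equal(fm$ranef_var, 0.16, tolerance = 0.5)
  expect_equal(cf$df, fm$n_obs - 2)

  # constant outcome: slopes vanish
  d$y <- 1
  fm0 <- fit_mixed(d, "y", "x")
  expect_equal(fm0$coefficients$estimate[2], 0, tolerance = 1e-8)
})

test_that("singular designs are rejected with the collinear column named", {
  d <- data.frame(subject_id = rep(c("a", "b"), each = 5),
                  x = rnorm(10))
  d$x2 <- 2 * d$x
  d$y <- rnorm(10)
  expect_error(fit_mixed(d, "y", c("x", "x2")), "x2")
  expect_error(fit_mixed(d[d$subject_id == "a", ], "y", "x"), "2 patients")
  expect_error(fit_mixed(d, "y", "nope"), "missing column")
})

test_that("the full developmental model uses the study's covariate coding", {
  cs <- cohort_spec(n_subjects = 40, curves = mi_only_curves(),
                    soz_shift = c(mi80_0.5_1 = 0.1), seed = 52)
  co <- simulate_cohort(cs)
  fm <- developmental_mixed_model(co$biomarkers, "mi80_0.5_1",
                                  co$sites, co$subjects)
  terms <- fm$coefficients$term
  expect_setequal(terms, c("(Intercept)", "age", "sex", "soz", "mri",
                           "hemisphere", "n_asm"))
  age_cf <- fm$coefficients[terms == "age", ]
  expect_gt(age_cf$estimate, 0)             # growth on the sqrt-age scale
  soz_cf <- fm$coefficients[terms == "soz", ]
  expect_gt(soz_cf$estimate, 0)             # the injected SOZ shift
  expect_equal(fm$coefficients$df[1], fm$n_obs - 7)
})

test_that("occipital enhancement is recovered in the stratum that has it", {
  # build a cohort where only the older stratum carries an occipital shift
  cs <- cohort_spec(n_subjects = 60, age_range = c(1, 12),
                    sites_per_lobe = c(frontal = 6, temporal = 6,
                                       parietal = 6, occipital = 6),
                    n_soz = 0, curves = flat_mi_curves(),
                    soz_shift = c(mi80_0.5_1 = 0), seed = 53)
  co <- simulate_cohort(cs)
  old <- co$subjects$age[match(co$sites$subject_id,
                               co$subjects$subject_id)] >= 4
  occ <- co$sites$lobe == "occipital"
  co$biomarkers$mi80_0.5_1[old & occ] <-
    co$biomarkers$mi80_0.5_1[old & occ] + 0.17
  res <- occipital_enhancement(co$biomarkers, co$sites, co$subjects)
  older <- res[res$stratum == "older", ]
  young <- res[res$stratum == "young", ]
  expect_false(older$flagged)
  expect_lt(older$ci_lo, 0.17); expect_gt(older$ci_hi, 0.17)
  expect_lt(young$ci_lo, 0); expect_gt(young$ci_hi, 0)
  expect_error(occipital_enhancement(co$biomarkers, co$sites, co$subjects,
                                     age_split = 0.1), "non-empty")
})

test_that("SOZ deviation test flags lobes without SOZ sites", {
  cs <- cohort_spec(n_subjects = 30, age_range = c(5, 10),
                    sites_per_lobe = c(frontal = 4, temporal = 4,
                                       parietal = 4, occipital = 4),
                    n_soz = 4, curves = flat_mi_curves(),
                    soz_shift = c(mi80_0.5_1 = 0.1), seed = 54)
  co <- simulate_cohort(cs)
  co$subjects$soz_lobes <- "frontal"     # mislabel: flags follow sites
  zt <- zscore_table(co$biomarkers, co$sites, co$subjects,
                     widen_if_short = TRUE)
  # drop SOZ sites from one lobe entirely
  drop <- co$sites$is_soz & co$sites$lobe == "temporal"
  co$sites$is_soz[drop] <- FALSE
  res <- soz_deviation_test(zt, co$sites, co$subjects)
  expect_equal(nrow(res), 4)
  expect_true(all(res$estimate[!res$flagged] > 0))
})

test_that("band-slope age dependence detects a monotone trend per lobe", {
  cs <- cohort_spec(n_subjects = 20, curves = mi_only_curves(), seed = 55)
  co <- simulate_cohort(cs)
  ages <- co$subjects$age[match(co$sites$subject_id, co$subjects$subject_id)]
  slopes <- data.frame(site_id = co$sites$site_id,
                       slope_per_hz = -0.01 - 0.001 * ages)
  res <- band_slope_age_dependence(slopes, co$sites, co$subjects)
  expect_equal(nrow(res), 4)
  expect_equal(res$rho, rep(-1, 4))
  expect_true(all(res$significant))
  # constant slopes flag the lobe
  slopes$slope_per_hz <- -0.01
  res2 <- band_slope_age_dependence(slopes, co$sites, co$subjects)
  expect_true(all(res2$flagged))
})
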