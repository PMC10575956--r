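test_that("the 10-mm interpolation radius is strict and averages coverage", {
  mesh <- make_sphere_mesh(1)
  v1 <- mesh$vertices[1, ]
  outward <- v1 / sqrt(sum(v1^2))
  mk_site <- function(dist, id) {
    p <- v1 + outward * dist
    data.frame(site_id = id, subject_id = "s1", x = p[1], y = p[2], z = p[3],
               lobe = "frontal", hemisphere = "left", is_soz = FALSE,
               is_spike_zone = FALSE, is_lesion = FALSE)
  }
  # 9.9 mm -> covered; 10.1 mm -> missing
  near <- map_sites_to_mesh(mk_site(9.9, "a"), 0.7, mesh)
  expect_equal(unname(near$vertex_values[1, 1]), 0.7)
  far <- suppressWarnings(map_sites_to_mesh(mk_site(10.1, "a"), 0.7, mesh))
  expect_true(is.na(far$vertex_values[1, 1]))
  # two covering electrodes average: (0.1 + 0.3) / 2
  two <- rbind(mk_site(5, "a"), mk_site(8, "b"))
  got <- map_sites_to_mesh(two, c(0.1, 0.3), mesh)
  expect_equal(unname(got$vertex_values[1, 1]), 0.2)
  # nothing anywhere near the mesh warns about empty coverage
  lost <- mk_site(0, "a"); lost$x <- 1e6
  expect_warning(map_sites_to_mesh(lost, 1, mesh), "coverage")
})

test_that("developmental regression recovers an exact generating model", {
  ages <- c(1, 2, 4, 9, 16, 25, 36)
  f <- fit_development(0.05 + 0.047 * sqrt(ages), ages, "sqrt_age")
  expect_equal(f$beta1, 0.047, tolerance = 1e-12)
  expect_equal(f$beta0, 0.05, tolerance = 1e-12)
  expect_equal(f$sigma, 0, tolerance = 1e-10)
  expect_equal(f$df, 5)

  fc <- fit_development(rep(0.3, 7), ages, "sqrt_age")
  expect_equal(fc$beta1, 0)
  expect_equal(fc$p, 1)

  expect_error(fit_development(1:5, rep(2, 5), "sqrt_age"), "constant")
  expect_error(fit_development(1:2, 1:2), "3 subjects")
  expect_error(fit_development(1:5, 1:5, "cube"), "unknown")
})

test_that("regression matches a normal-equations oracle to 1e-10", {
  set.seed(30)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    ages <- exp(runif(n, 0, 3.5))
    y <- rnorm(n)
    tr <- sample(c("age", "sqrt_age", "log10_age"), 1)
    f <- fit_development(y, ages, tr)
    ta <- switch(tr, age = ages, sqrt_age = sqrt(ages),
                 log10_age = log10(ages))
    X <- cbind(1, ta)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(f$beta0, beta[1], tolerance = 1e-10)
    expect_equal(f$beta1, beta[2], tolerance = 1e-10)
    res <- y - X %*% beta
    s2 <- sum(res^2) / (n - 2)
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    expect_equal(f$se, se, tolerance = 1e-10)
  }
})

test_that("Benjamini-Hochberg selection follows the step-up rule", {
  expect_identical(fdr_select(rep(1, 5)), rep(FALSE, 5))
  expect_identical(fdr_select(c(0.001, 0.02, 0.9)), c(TRUE, TRUE, FALSE))
  expect_identical(fdr_select(numeric(0)), logical(0))
  expect_error(fdr_select(c(0.5, 1.2)), "\\[0, 1\\]")
  # a family of six measures x three transforms has size 18
  p <- rep(0.04, 18)
  expect_length(fdr_select(p), 18)
})

test_that("atlas prediction evaluates the fitted curves", {
  ages <- c(1, 2.25, 4, 9, 16, 25, 36.5)
  set.seed(31)
  pv <- rbind(0.05 + 0.047 * sqrt(ages) + rnorm(7, 0, 1e-4),
              0.2 - 0.01 * sqrt(ages) + rnorm(7, 0, 1e-4))
  colnames(pv) <- sprintf("s%d", 1:7)
  fits <- fit_atlas(pv, ages, transforms = "sqrt_age")
  pred4 <- predict_atlas(fits, 4)
  expect_equal(unname(pred4[1]), 0.05 + 0.047 * 2, tolerance = 1e-3)
  up <- predict_atlas(fits, 4, kind = "mean_plus_2sd")
  expect_equal(unname(up - pred4),
               2 * fits$sigma[fits$transform == "sqrt_age"])
  # age 0 with sqrt transform gives the intercept, flagged as extrapolation
  expect_warning(p0 <- predict_atlas(fits, 0), "outside")
  expect_equal(unname(p0), fits$beta0, tolerance = 1e-12)
})

test_that("AIC ranks the generating transform best at high signal", {
  set.seed(32)
  ages <- exp(runif(114, log(1), log(41.5)))
  v <- 0.05 + 0.047 * sqrt(ages) + rnorm(114, 0, 0.01)
  pv <- matrix(v, nrow = 1, dimnames = list(NULL, sprintf("s%d", 1:114)))
  fits <- fit_atlas(pv, ages)
  best <- aic_best_transform(fits)
  expect_equal(best$transform, "sqrt_age")
})

test_that("uncovered mesh points are absent from the atlas", {
  ages <- c(1, 4, 9, 16)
  pv <- rbind(sqrt(ages), rep(NA_real_, 4))
  colnames(pv) <- sprintf("s%d", 1:4)
  fits <- fit_atlas(pv, ages, transforms = "sqrt_age")
  expect_identical(unique(fits$point), 1L)
  expect_length(predict_atlas(fits, 4), 1)
})
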