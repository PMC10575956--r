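# Normative developmental atlas: project per-site biomarkers onto the
# surface mesh (10-mm interpolation), fit per-mesh-point regressions of the
# biomarker on a transform of age, select transforms by AIC, control the
# false discovery rate, and predict normative mean / mean + 2 SD maps at any
# age.

age_transform_fun <- function(transform) {
  switch(transform,
         age = identity,
         sqrt_age = sqrt,
         log10_age = log10,
         stop("unknown age transform: ", transform))
}

#' Project electrode values onto the mesh
#'
#' Each vertex within \code{radius_mm} (Euclidean) of at least one electrode
#' takes, per subject, the mean value of that subject's covering electrodes;
#' uncovered vertices are missing. A mesh point's per-subject value is the
#' mean over its non-missing vertices, so each subject contributes at most
#' one value per mesh point (no pseudo-replication).
#'
#' @param sites sites table (site_id, subject_id, x, y, z).
#' @param values numeric vector aligned with \code{sites} rows.
#' @param mesh a \code{surface_mesh}.
#' @param radius_mm interpolation radius (default 10; boundary inclusive).
#' @return list: \code{vertex_values} (vertices x subjects) and
#'   \code{point_values} (mesh points x subjects), both with NA where
#'   uncovered, columns named by subject.
#' @export
map_sites_to_mesh <- function(sites, values, mesh, radius_mm = 10) {
  stopifnot(inherits(mesh, "surface_mesh"), length(values) == nrow(sites))
  subjects <- unique(sites$subject_id)
  nv <- nrow(mesh$vertices)
  vv <- matrix(NA_real_, nrow = nv, ncol = length(subjects),
               dimnames = list(NULL, subjects))
  vt <- t(mesh$vertices)
  any_cover <- FALSE
  for (s in seq_along(subjects)) {
    rows <- which(sites$subject_id == subjects[s])
    if (length(rows) == 0) next
    sums <- numeric(nv)
    cnts <- numeric(nv)
    for (r in rows) {
      d <- sqrt(colSums((vt - c(sites$x[r], sites$y[r], sites$z[r]))^2))
      hit <- d <= radius_mm
      sums[hit] <- sums[hit] + values[r]
      cnts[hit] <- cnts[hit] + 1
    }
    cov <- cnts > 0
    if (any(cov)) any_cover <- TRUE
    vv[cov, s] <- sums[cov] / cnts[cov]
  }
  if (!any_cover) warning("no electrode lies within ", radius_mm,
                          " mm of any mesh vertex: empty coverage")
  pv <- do.call(rbind, lapply(mesh$patches, function(ix) {
    colMeans(vv[ix, , drop = FALSE], na.rm = TRUE)
  }))
  pv[!is.finite(pv)] <- NA_real_
  colnames(pv) <- subjects
  list(vertex_values = vv, point_values = pv)
}

#' Developmental regression at one mesh point
#'
#' Ordinary least squares of a biomarker value on a transform of age (age,
#' sqrt(age) or log10(age)); t = slope/SE on n - 2 residual degrees of
#' freedom; AIC under the full Gaussian likelihood (constants included,
#' k = 3 parameters).
#'
#' @param values per-subject biomarker values.
#' @param ages subject ages, years.
#' @param transform one of \code{"age", "sqrt_age", "log10_age"}.
#' @return one-row data.frame: \code{transform, beta0, beta1, se, t, p, df,
#'   ci_lo, ci_hi, sigma, aic, n}.
#' @export
fit_development <- function(values, ages, transform = "sqrt_age") {
  ok <- is.finite(values) & is.finite(ages)
  values <- values[ok]; ages <- ages[ok]
  n <- length(values)
  if (n < 3) stop("need at least 3 subjects with coverage")
  ta <- age_transform_fun(transform)(ages)
  if (stats::sd(ta) == 0) stop("constant transformed age: slope undefined")
  if (stats::sd(values) == 0) {
    # constant outcome: slope exactly 0, no evidence against the null
    fit0 <- stats::lm(values ~ ta)
    return(data.frame(transform = transform, beta0 = values[1], beta1 = 0,
                      se = 0, t = 0, p = 1, df = n - 2, ci_lo = 0, ci_hi = 0,
                      sigma = 0, aic = stats::AIC(fit0), n = n,
                      stringsAsFactors = FALSE))
  }
  fit <- stats::lm(values ~ ta)
  sm <- suppressWarnings(summary(fit))
  beta <- stats::coef(fit)
  se <- sm$coefficients[2, 2]
  df <- n - 2
  if (se == 0) {
    # degenerate exact fit: constant outcome (slope 0, no evidence) or a
    # perfectly linear one (slope recovered exactly)
    tval <- if (beta[2] == 0) 0 else sign(beta[2]) * Inf
    p <- if (beta[2] == 0) 1 else 0
  } else {
    tval <- beta[2] / se
    p <- 2 * stats::pt(-abs(tval), df)
  }
  tc <- stats::qt(0.975, df)
  data.frame(transform = transform,
             beta0 = unname(beta[1]), beta1 = unname(beta[2]),
             se = se, t = unname(tval), p = unname(p), df = df,
             ci_lo = unname(beta[2] - tc * se),
             ci_hi = unname(beta[2] + tc * se),
             sigma = sm$sigma, aic = stats::AIC(fit), n = n,
             stringsAsFactors = FALSE)
}

#' Fit the normative atlas over all mesh points and age transforms
#'
#' @param point_values mesh points x subjects matrix from
#'   \code{\link{map_sites_to_mesh}} (columns named by subject).
#' @param ages per-subject ages aligned with the columns.
#' @param transforms age transforms to fit.
#' @param min_n minimum covered subjects per mesh point (default 3).
#' @return object of class \code{atlas_model}: data.frame of fits (one row
#'   per mesh point x transform; unfittable points absent) with the fitted
#'   age range as an attribute.
#' @export
fit_atlas <- function(point_values, ages,
                      transforms = c("age", "sqrt_age", "log10_age"),
                      min_n = 3) {
  stopifnot(ncol(point_values) == length(ages))
  rows <- list()
  for (pt in seq_len(nrow(point_values))) {
    v <- point_values[pt, ]
    ok <- is.finite(v)
    if (sum(ok) < min_n) next
    for (tr in transforms) {
      r <- fit_development(v[ok], ages[ok], tr)
      r$point <- pt
      rows[[length(rows) + 1L]] <- r
    }
  }
  fits <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(transform = character(0), beta0 = numeric(0),
               beta1 = numeric(0), se = numeric(0), t = numeric(0),
               p = numeric(0), df = numeric(0), ci_lo = numeric(0),
               ci_hi = numeric(0), sigma = numeric(0), aic = numeric(0),
               n = numeric(0), point = integer(0))
  attr(fits, "age_range") <- range(ages)
  class(fits) <- c("atlas_model", "data.frame")
  fits
}

#' Benjamini-Hochberg significance selection
#'
#' Step-up false-discovery-rate control at level \code{q} over one stated
#' comparison family (the lobe/mesh developmental scans use a family of 18:
#' six biomarker measures x three age transforms).
#'
#' @param pvalues p-values in [0, 1] (the family).
#' @param q FDR level (default 0.05).
#' @return logical mask, TRUE where selected; empty input gives an empty
#'   mask.
#' @export
fdr_select <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Best age transform per mesh point by AIC
#'
#' @param fits an \code{atlas_model}.
#' @return data.frame (point, transform) with the AIC-minimizing transform.
#' @export
aic_best_transform <- function(fits) {
  out <- do.call(rbind, lapply(split(as.data.frame(fits), fits$point),
                               function(d) d[which.min(d$aic),
                                             c("point", "transform")]))
  rownames(out) <- NULL
  out
}

#' Predict a normative atlas at an age
#'
#' \code{mean} gives \code{beta0 + beta1 * transform(age)} per mesh point;
#' \code{mean_plus_2sd} adds two residual standard deviations (the upper
#' normative band). Ages outside the fitted range are allowed but flagged
#' with a warning.
#'
#' @param fits an \code{atlas_model}, restricted to one transform (or pass
#'   \code{transform}).
#' @param age years.
#' @param kind \code{"mean"} or \code{"mean_plus_2sd"}.
#' @param transform which transform's fits to use (default: the only one
#'   present).
#' @return named numeric vector of per-mesh-point values (names = point
#'   index); unfitted mesh points are simply absent.
#' @export
predict_atlas <- function(fits, age, kind = c("mean", "mean_plus_2sd"),
                          transform = NULL) {
  kind <- match.arg(kind)
  d <- as.data.frame(fits)
  if (!is.null(transform)) d <- d[d$transform == transform, ]
  if (length(unique(d$transform)) > 1) {
    stop("fits contain several transforms; pass `transform`")
  }
  ar <- attr(fits, "age_range")
  if (!is.null(ar) && (age < ar[1] || age > ar[2])) {
    warning("age ", age, " lies outside the fitted range [",
            round(ar[1], 2), ", ", round(ar[2], 2), "]: extrapolating")
  }
  ta <- age_transform_fun(d$transform[1])(age)
  v <- d$beta0 + d$beta1 * ta
  if (kind == "mean_plus_2sd") v <- v + 2 * d$sigma
  stats::setNames(v, d$point)
}
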