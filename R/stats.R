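# Group-level inference. The mixed-model solver is lme4 (maximum
# likelihood); this module's contract is the model specification, the
# covariate coding (female = 1, SOZ = 1, lesion = 1, left = 1), the
# residual-DF convention (n - p, matching the printed-table style), and the
# multiple-testing bookkeeping.

#' Linear mixed model with a per-patient random intercept
#'
#' Fits \code{outcome ~ 1 + <fixed> + (1 | group)} by maximum likelihood and
#' reports Wald t statistics on residual degrees of freedom
#' \code{DF = n_obs - n_fixed}; 95% CI = estimate +/- t(0.975, DF) * SE.
#'
#' @param data data.frame of observations.
#' @param outcome outcome column name.
#' @param fixed character vector of fixed-effect column names.
#' @param group grouping column (patient) for the random intercept.
#' @param constrain_zero_ranef pin the random-intercept variance at zero, in
#'   which case the model reduces exactly to ordinary least squares on the
#'   fixed effects (same coding and DF convention).
#' @return object of class \code{mixed_model_result}: list with
#'   \code{coefficients} (term, estimate, se, t, df, p, ci_lo, ci_hi),
#'   \code{ranef_var}, \code{resid_var}, \code{n_obs}, \code{n_groups},
#'   \code{formula}.
#' @export
fit_mixed <- function(data, outcome, fixed, group = "subject_id",
                      constrain_zero_ranef = FALSE) {
  miss <- setdiff(c(outcome, fixed, group), names(data))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (length(unique(data[[group]])) < 2) stop("need at least 2 patients")
  X <- stats::model.matrix(
    stats::reformulate(fixed, intercept = TRUE), data = data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  if (constrain_zero_ranef) {
    ofml <- stats::as.formula(paste(outcome, "~ 1 +",
                                    paste(fixed, collapse = " + ")))
    fit <- stats::lm(ofml, data = data)
    b <- stats::coef(fit)
    V <- stats::vcov(fit)
    n <- length(stats::resid(fit))
    ranef_var <- 0
    resid_var <- sum(stats::resid(fit)^2) / n
    fml_txt <- paste(deparse(ofml), "[random-intercept variance pinned at 0]")
  } else {
    fml <- stats::as.formula(paste(outcome, "~ 1 +",
                                   paste(fixed, collapse = " + "),
                                   "+ (1 |", group, ")"))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = data, REML = FALSE)))
    b <- lme4::fixef(fit)
    # degenerate fits (e.g. a constant outcome) have no usable vcov
    V <- suppressWarnings(
      tryCatch(as.matrix(stats::vcov(fit)), error = function(e) NULL))
    if (is.null(V) || anyNA(V)) V <- matrix(0, length(b), length(b))
    n <- stats::nobs(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    ranef_var <- vc$vcov[vc$grp == group][1]
    resid_var <- vc$vcov[vc$grp == "Residual"][1]
    fml_txt <- deparse(fml)
  }
  se <- sqrt(diag(V))
  p <- length(b)
  df <- n - p
  tval <- ifelse(se > 0, b / se, ifelse(abs(b) < 1e-12, 0, sign(b) * Inf))
  pval <- ifelse(se > 0, 2 * stats::pt(-abs(tval), df),
                 ifelse(abs(b) < 1e-12, 1, 0))
  tc <- stats::qt(0.975, df)
  structure(list(
    coefficients = data.frame(term = names(b), estimate = unname(b),
                              se = unname(se), t = unname(tval), df = df,
                              p = unname(pval),
                              ci_lo = unname(b - tc * se),
                              ci_hi = unname(b + tc * se),
                              stringsAsFactors = FALSE),
    ranef_var = ranef_var,
    resid_var = resid_var,
    n_obs = n,
    n_groups = length(unique(data[[group]])),
    formula = fml_txt),
    class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(x$formula, "\n")
  cat(sprintf("n = %d observations, %d patients; random-intercept var %.4g\n",
              x$n_obs, x$n_groups, x$ranef_var))
  print(x$coefficients, digits = 4)
  invisible(x)
}

# Per-site covariate frame with the published coding conventions.
code_covariates <- function(sites, subjects, age_transform = "sqrt_age") {
  m <- match(sites$subject_id, subjects$subject_id)
  if (anyNA(m)) stop("sites reference unknown subjects")
  data.frame(
    site_id = sites$site_id,
    subject_id = sites$subject_id,
    age = age_transform_fun(age_transform)(subjects$age[m]),
    sex = as.integer(subjects$sex[m] == "female"),
    soz = as.integer(sites$is_soz),
    mri = as.integer(subjects$has_mri_lesion[m]),
    hemisphere = as.integer(sites$hemisphere == "left"),
    n_asm = subjects$n_asm[m],
    lobe = sites$lobe,
    occipital = as.integer(sites$lobe == "occipital"),
    stringsAsFactors = FALSE)
}

#' Developmental mixed model for one biomarker
#'
#' The full covariate model:
#' \code{value ~ 1 + age + sex + SOZ + MRI + hemisphere + n_asm +
#' (1 | patient)} with age entered on a chosen transform scale.
#'
#' @param biomarkers biomarker table.
#' @param measure biomarker column.
#' @param sites,subjects cohort tables.
#' @param age_transform transform applied to age.
#' @return a \code{mixed_model_result}.
#' @export
developmental_mixed_model <- function(biomarkers, measure, sites, subjects,
                                      age_transform = "sqrt_age") {
  d <- code_covariates(sites, subjects, age_transform)
  d$value <- biomarkers[[measure]][match(d$site_id, biomarkers$site_id)]
  fit_mixed(d, "value", c("age", "sex", "soz", "mri", "hemisphere", "n_asm"))
}

#' Occipital physiological enhancement by age stratum
#'
#' Fits \code{value ~ 1 + occipital + (1 | patient)} separately below and at
#' or above the age split (default 4.0 years) for each measure, with
#' Benjamini-Hochberg correction over the measures within each stratum.
#'
#' @param biomarkers biomarker table.
#' @param sites,subjects cohort tables.
#' @param measures biomarker columns (the study family has six).
#' @param age_split years (default 4.0).
#' @param q FDR level.
#' @return data.frame: stratum, measure, estimate, se, t, df, p, ci_lo,
#'   ci_hi, p_fdr_significant, flagged (TRUE when a stratum lacks occipital
#'   sites or subjects).
#' @export
occipital_enhancement <- function(biomarkers, sites, subjects,
                                  measures = setdiff(names(biomarkers),
                                                     "site_id"),
                                  age_split = 4.0, q = 0.05) {
  d0 <- code_covariates(sites, subjects)
  age_years <- subjects$age[match(d0$subject_id, subjects$subject_id)]
  strata <- list(young = age_years < age_split,
                 older = age_years >= age_split)
  if (!any(strata$young) || !any(strata$older)) {
    stop("both age strata must be non-empty at split ", age_split)
  }
  rows <- list()
  for (st in names(strata)) {
    sel <- strata[[st]]
    res <- lapply(measures, function(bm) {
      d <- d0[sel, ]
      d$value <- biomarkers[[bm]][match(d$site_id, biomarkers$site_id)]
      if (sum(d$occipital) == 0 || length(unique(d$subject_id)) < 2) {
        return(data.frame(stratum = st, measure = bm, estimate = NA_real_,
                          se = NA_real_, t = NA_real_, df = NA_real_,
                          p = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                          flagged = TRUE, stringsAsFactors = FALSE))
      }
      fit <- fit_mixed(d, "value", "occipital")
      cf <- fit$coefficients[fit$coefficients$term == "occipital", ]
      data.frame(stratum = st, measure = bm, estimate = cf$estimate,
                 se = cf$se, t = cf$t, df = cf$df, p = cf$p,
                 ci_lo = cf$ci_lo, ci_hi = cf$ci_hi, flagged = FALSE,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    sig <- rep(NA, nrow(res))
    okp <- !is.na(res$p)
    sig[okp] <- fdr_select(res$p[okp], q)
    res$significant <- sig
    rows[[st]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' SOZ deviation test per lobe and biomarker
#'
#' For each lobe and biomarker: \code{z ~ 1 + SOZ + (1 | patient)} on the
#' z-scored table, Benjamini-Hochberg over the biomarkers within each lobe
#' (the study family has six measures).
#'
#' @param ztab long z-score table from \code{\link{zscore_table}}.
#' @param sites,subjects cohort tables.
#' @param q FDR level.
#' @return data.frame: lobe, biomarker, estimate, se, t, df, p, ci_lo,
#'   ci_hi, significant, flagged (lobes without SOZ sites are flagged).
#' @export
soz_deviation_test <- function(ztab, sites, subjects, q = 0.05) {
  d0 <- code_covariates(sites, subjects)
  rows <- list()
  for (lb in sort(unique(d0$lobe))) {
    res <- lapply(sort(unique(ztab$biomarker)), function(bm) {
      zt <- ztab[ztab$biomarker == bm, ]
      d <- d0[d0$lobe == lb, ]
      d$z <- zt$z[match(d$site_id, zt$site_id)]
      d <- d[is.finite(d$z), ]
      if (nrow(d) == 0 || sum(d$soz) == 0 ||
          length(unique(d$subject_id)) < 2) {
        return(data.frame(lobe = lb, biomarker = bm, estimate = NA_real_,
                          se = NA_real_, t = NA_real_, df = NA_real_,
                          p = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                          flagged = TRUE, stringsAsFactors = FALSE))
      }
      fit <- fit_mixed(d, "z", "soz")
      cf <- fit$coefficients[fit$coefficients$term == "soz", ]
      data.frame(lobe = lb, biomarker = bm, estimate = cf$estimate,
                 se = cf$se, t = cf$t, df = cf$df, p = cf$p,
                 ci_lo = cf$ci_lo, ci_hi = cf$ci_hi, flagged = FALSE,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    sig <- rep(NA, nrow(res))
    okp <- !is.na(res$p)
    sig[okp] <- fdr_select(res$p[okp], q)
    res$significant <- sig
    rows[[lb]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Age dependence of the MI band-profile slope, per lobe
#'
#' Aggregates per-site band-profile slopes to one value per subject and
#' lobe, then tests the Spearman correlation of that slope with age in each
#' lobe, Benjamini-Hochberg over the four lobes.
#'
#' @param slopes data.frame (site_id, slope_per_hz).
#' @param sites,subjects cohort tables.
#' @param q FDR level.
#' @return data.frame: lobe, rho, p, n_subjects, significant, flagged
#'   (constant slopes flag the lobe).
#' @export
band_slope_age_dependence <- function(slopes, sites, subjects, q = 0.05) {
  m <- match(slopes$site_id, sites$site_id)
  d <- data.frame(subject_id = sites$subject_id[m], lobe = sites$lobe[m],
                  slope = slopes$slope_per_hz, stringsAsFactors = FALSE)
  agg <- stats::aggregate(slope ~ subject_id + lobe, data = d, FUN = mean)
  agg$age <- subjects$age[match(agg$subject_id, subjects$subject_id)]
  rows <- lapply(sort(unique(agg$lobe)), function(lb) {
    a <- agg[agg$lobe == lb, ]
    if (nrow(a) < 3) {
      return(data.frame(lobe = lb, rho = NA_real_, p = NA_real_,
                        n_subjects = nrow(a), flagged = TRUE))
    }
    if (stats::sd(a$slope) == 0) {
      return(data.frame(lobe = lb, rho = NA_real_, p = NA_real_,
                        n_subjects = nrow(a), flagged = TRUE))
    }
    ct <- onset_age_correlation(a$slope, a$age)
    data.frame(lobe = lb, rho = ct$rho, p = ct$pvalue,
               n_subjects = nrow(a), flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  sig <- rep(NA, nrow(out))
  okp <- !is.na(out$p)
  sig[okp] <- fdr_select(out$p[okp], q)
  out$significant <- sig
  rownames(out) <- NULL
  out
}
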