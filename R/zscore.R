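# Normative z-score deviation: a site's biomarker against the 30 spatially
# nearest nonepileptic sites of other subjects inside a forward age window
# [n, n + 3.9] years (n = the query subject's age). The forward window is
# implemented exactly as specified; a symmetric variant is available.

#' Age-windowed nearest-neighbour normative reference
#'
#' Restricts the cohort to nonepileptic sites of other subjects whose age
#' lies in \code{[n, n + window]} (or \code{[n - window/2, n + window/2]}
#' when \code{symmetric}), then takes the \code{k} sites with the smallest
#' Euclidean distance to the query contact, ties broken by site_id order.
#'
#' @param query_xyz length-3 coordinates, mm.
#' @param query_age query subject's age, years.
#' @param query_subject query subject id (own sites are excluded).
#' @param sites cohort sites table.
#' @param values biomarker values aligned with \code{sites} rows.
#' @param subjects subject profiles (for ages).
#' @param k reference size (default 30).
#' @param window forward window width in years (default 3.9).
#' @param symmetric centre the window on the query age instead.
#' @param widen_if_short if TRUE, widen the window symmetrically in 1-year
#'   steps until \code{k} sites are eligible (result flagged); if FALSE
#'   (default), fewer than \code{k} eligible sites is an error.
#' @return list \code{(mean, sd, site_ids, widened)}; \code{sd} uses the
#'   n - 1 denominator.
#' @export
normative_reference <- function(query_xyz, query_age, query_subject,
                                sites, values, subjects, k = 30,
                                window = 3.9, symmetric = FALSE,
                                widen_if_short = FALSE) {
  stopifnot(length(query_xyz) == 3, length(values) == nrow(sites))
  ages <- subjects$age[match(sites$subject_id, subjects$subject_id)]
  base_ok <- is_nonepileptic(sites) & sites$subject_id != query_subject &
    is.finite(values)
  lo0 <- if (symmetric) query_age - window / 2 else query_age
  hi0 <- if (symmetric) query_age + window / 2 else query_age + window
  widen <- 0
  repeat {
    ok <- base_ok & ages >= lo0 - widen & ages <= hi0 + widen
    if (sum(ok) >= k) break
    if (!widen_if_short) {
      stop("only ", sum(ok), " eligible reference sites in the age window [",
           round(lo0, 1), ", ", round(hi0, 1), "]; need ", k)
    }
    widen <- widen + 1
    if (widen > 200) stop("cannot assemble a reference of size ", k)
  }
  idx <- which(ok)
  d <- sqrt((sites$x[idx] - query_xyz[1])^2 +
            (sites$y[idx] - query_xyz[2])^2 +
            (sites$z[idx] - query_xyz[3])^2)
  ord <- order(d, sites$site_id[idx])
  chosen <- idx[ord[seq_len(k)]]
  list(mean = mean(values[chosen]), sd = stats::sd(values[chosen]),
       site_ids = sites$site_id[chosen], widened = widen > 0)
}

#' z-score of a raw value against a normative reference
#'
#' @param raw observed biomarker value.
#' @param reference list from \code{\link{normative_reference}}.
#' @return list of class \code{deviation_score}: \code{z, raw, ref_mean,
#'   ref_sd, n_ref, site_ids, undefined} (\code{undefined} when the
#'   reference SD is zero).
#' @export
zscore <- function(raw, reference) {
  undefined <- !is.finite(reference$sd) || reference$sd <= 0
  z <- if (undefined) NA_real_ else (raw - reference$mean) / reference$sd
  structure(list(z = z, raw = raw, ref_mean = reference$mean,
                 ref_sd = reference$sd, n_ref = length(reference$site_ids),
                 site_ids = reference$site_ids, undefined = undefined),
            class = "deviation_score")
}

#' z-score a whole biomarker table
#'
#' Computes the deviation score of every site (SOZ and nonepileptic alike)
#' for each biomarker column, against its own nearest-30 age-windowed
#' nonepileptic reference.
#'
#' @param biomarkers biomarker table (site_id + numeric columns).
#' @param sites sites table.
#' @param subjects subject profiles.
#' @param measures biomarker columns to score (default: all numeric).
#' @param ... passed to \code{\link{normative_reference}}.
#' @return long data.frame: \code{site_id, biomarker, raw, ref_mean, ref_sd,
#'   z, undefined, widened}.
#' @export
zscore_table <- function(biomarkers, sites, subjects,
                         measures = setdiff(names(biomarkers), "site_id"),
                         ...) {
  ord <- match(sites$site_id, biomarkers$site_id)
  if (anyNA(ord)) stop("sites and biomarker table disagree on site ids")
  out <- list()
  for (bm in measures) {
    vals <- biomarkers[[bm]][ord]
    for (i in seq_len(nrow(sites))) {
      ref <- normative_reference(
        c(sites$x[i], sites$y[i], sites$z[i]),
        subjects$age[match(sites$subject_id[i], subjects$subject_id)],
        sites$subject_id[i], sites, vals, subjects, ...)
      zs <- zscore(vals[i], ref)
      out[[length(out) + 1L]] <- data.frame(
        site_id = sites$site_id[i], biomarker = bm, raw = zs$raw,
        ref_mean = zs$ref_mean, ref_sd = zs$ref_sd, z = zs$z,
        undefined = zs$undefined, widened = ref$widened,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
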