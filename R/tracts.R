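# Co-growth over white-matter streamlines. Fiber tracking is consumed, not
# performed: the input is a table of precomputed streamline endpoints with a
# tract label and the fraction of the streamline's coordinates inside that
# tract.

#' White-matter tracts admitted to the co-growth analysis
#' @export
allowed_tract_labels <- function() {
  c("arcuate fasciculus", "cingulum", "corpus callosum", "extreme capsule",
    "frontal aslant tract", "inferior fronto-occipital fasciculus",
    "inferior longitudinal fasciculus", "middle longitudinal fasciculus",
    "superior longitudinal fasciculus", "uncinate fasciculus",
    "vertical occipital fasciculus")
}

#' Read a streamline endpoint table
#'
#' TSV with columns \code{ax, ay, az, bx, by, bz, tract, fraction}
#' (endpoint coordinates in mm, tract label, fraction of coordinates inside
#' the tract).
#'
#' @param path TSV path.
#' @return data.frame of streamline records.
#' @export
read_streamlines <- function(path) {
  tab <- tsv_read(path)
  need <- c("ax", "ay", "az", "bx", "by", "bz", "tract", "fraction")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("streamline table missing column(s): ",
                             paste(miss, collapse = ", "))
  for (cc in need[1:6]) tab[[cc]] <- as.numeric(tab[[cc]])
  if (any(!is.finite(as.matrix(tab[, need[1:6]])))) {
    stop("non-finite streamline endpoint coordinate")
  }
  tab$fraction <- as.numeric(tab$fraction)
  if (any(tab$fraction < 0 | tab$fraction > 1)) {
    stop("tract fraction must lie in [0, 1]")
  }
  tab
}

#' @rdname read_streamlines
#' @param records streamline records data.frame.
#' @export
write_streamlines <- function(records, path) tsv_write(records, path)

#' Keep streamlines with sufficient tract membership
#'
#' Retains records whose in-tract fraction is at least \code{min_fraction}
#' (boundary inclusive: exactly 50% is kept) and whose tract is on the
#' allowed list.
#'
#' @param records streamline records.
#' @param min_fraction minimum in-tract fraction (default 0.5).
#' @param allowed_tracts admitted tract labels.
#' @return filtered records.
#' @export
filter_streamlines <- function(records, min_fraction = 0.5,
                               allowed_tracts = allowed_tract_labels()) {
  keep <- records$fraction >= min_fraction &
    tolower(records$tract) %in% tolower(allowed_tracts)
  records[keep, , drop = FALSE]
}

#' Co-growth edges from streamline endpoints
#'
#' An edge exists when both endpoints of a streamline fall within
#' \code{seed_radius} mm of significant mesh points, the two mesh points are
#' distinct, and their developmental slopes share a sign. Edge intensity is
#' \eqn{\sqrt{|slope_a|}\,\sqrt{|slope_b|}}; the sign classifies the pair as
#' co-growth (both positive) or co-diminution (both negative).
#'
#' @param records (filtered) streamline records.
#' @param mesh a \code{surface_mesh} (patch centroids are the mesh-point
#'   locations).
#' @param slopes per-mesh-point developmental slopes (length = number of
#'   patches).
#' @param significant logical mask of significant mesh points.
#' @param seed_radius matching radius, mm (default 4).
#' @return data.frame of edges \code{(point_a, point_b, tract, intensity,
#'   sign)} with \code{point_a < point_b}; the number of records whose
#'   endpoints matched no seed is in attribute \code{"n_skipped"}. Edges are
#'   independent of record order (output sorted).
#' @export
attach_endpoints <- function(records, mesh, slopes, significant,
                             seed_radius = 4) {
  stopifnot(inherits(mesh, "surface_mesh"),
            length(slopes) == length(mesh$patches),
            length(significant) == length(mesh$patches))
  centers <- mesh$patch_centers[significant, , drop = FALSE]
  cand <- which(significant)
  match_point <- function(xyz) {
    if (length(cand) == 0) return(NA_integer_)
    d <- sqrt(colSums((t(centers) - xyz)^2))
    j <- which.min(d)
    if (d[j] <= seed_radius) cand[j] else NA_integer_
  }
  edges <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(records))) {
    pa <- match_point(c(records$ax[i], records$ay[i], records$az[i]))
    pb <- match_point(c(records$bx[i], records$by[i], records$bz[i]))
    if (is.na(pa) || is.na(pb)) { n_skipped <- n_skipped + 1L; next }
    if (pa == pb) next
    sa <- slopes[pa]; sb <- slopes[pb]
    if (sign(sa) != sign(sb) || sa == 0 || sb == 0) next
    edges[[length(edges) + 1L]] <- data.frame(
      point_a = min(pa, pb), point_b = max(pa, pb),
      tract = records$tract[i],
      intensity = sqrt(abs(sa)) * sqrt(abs(sb)),
      sign = if (sa > 0) "growth" else "diminution",
      stringsAsFactors = FALSE)
  }
  out <- if (length(edges) > 0) {
    e <- do.call(rbind, edges)
    e <- unique(e)
    e[order(e$point_a, e$point_b, e$tract), , drop = FALSE]
  } else {
    data.frame(point_a = integer(0), point_b = integer(0),
               tract = character(0), intensity = numeric(0),
               sign = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}
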