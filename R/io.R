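# Tabular I/O in the BIDS-iEEG TSV dialect: UTF-8, tab-separated, "n/a" for
# missing values. Coordinates are millimetres in one shared template space;
# no coordinate transform is ever applied here.

LOBES <- c("frontal", "temporal", "parietal", "occipital")

tsv_read <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "n/a", check.names = FALSE)
}

tsv_write <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "n/a"
      out[[j]] <- v
    } else {
      out[[j]] <- as.character(out[[j]])
      out[[j]][is.na(out[[j]])] <- "n/a"
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  if (is.numeric(x)) return(ifelse(is.na(x), FALSE, x != 0))
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("1", "true", "yes", "y")
  out
}

#' Read an electrode-sites table
#'
#' Expects a BIDS-style \code{*_electrodes.tsv} dialect with columns
#' \code{name, x, y, z, lobe, hemisphere} and optional status flags
#' \code{is_soz, is_spike_zone, is_lesion} (absent flags default to FALSE).
#' An optional \code{subject} column carries the subject id. Lobe and
#' hemisphere labels are case-normalized. Unknown extra columns are ignored
#' with a warning.
#'
#' A site is "nonepileptic" iff all three status flags are FALSE (outside the
#' seizure onset zone, the interictal spike zone, and any MRI-visible lesion).
#'
#' @param path TSV path.
#' @return data.frame with columns \code{site_id, subject_id, x, y, z, lobe,
#'   hemisphere, is_soz, is_spike_zone, is_lesion}.
#' @export
read_sites <- function(path) {
  tab <- tsv_read(path)
  mandatory <- c("name", "x", "y", "z", "lobe", "hemisphere")
  missing_cols <- setdiff(mandatory, names(tab))
  if (length(missing_cols) > 0) {
    stop("electrodes table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  known <- c(mandatory, "subject", "is_soz", "is_spike_zone", "is_lesion",
             "soz", "spike", "lesion")
  extra <- setdiff(names(tab), known)
  if (length(extra) > 0) {
    warning("ignoring unknown electrode column(s): ",
            paste(extra, collapse = ", "))
  }
  for (cc in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf("non-finite coordinate '%s' at row %d", cc, bad[1]))
    }
    tab[[cc]] <- v
  }
  lobe <- tolower(trimws(tab$lobe))
  bad_lobe <- which(!lobe %in% LOBES)
  if (length(bad_lobe) > 0) {
    stop(sprintf("unknown lobe '%s' at row %d", tab$lobe[bad_lobe[1]],
                 bad_lobe[1]))
  }
  hemi <- tolower(trimws(tab$hemisphere))
  if (!all(hemi %in% c("left", "right"))) stop("hemisphere must be left/right")
  pick_flag <- function(primary, alias) {
    if (primary %in% names(tab)) parse_flag(tab[[primary]])
    else if (alias %in% names(tab)) parse_flag(tab[[alias]])
    else rep(FALSE, nrow(tab))
  }
  data.frame(
    site_id = as.character(tab$name),
    subject_id = if ("subject" %in% names(tab)) as.character(tab$subject)
                 else rep(NA_character_, nrow(tab)),
    x = tab$x, y = tab$y, z = tab$z,
    lobe = lobe, hemisphere = hemi,
    is_soz = pick_flag("is_soz", "soz"),
    is_spike_zone = pick_flag("is_spike_zone", "spike"),
    is_lesion = pick_flag("is_lesion", "lesion"),
    stringsAsFactors = FALSE)
}

#' @rdname read_sites
#' @param sites a sites data.frame as returned by \code{read_sites}.
#' @export
write_sites <- function(sites, path) {
  out <- data.frame(name = sites$site_id, subject = sites$subject_id,
                    x = sites$x, y = sites$y, z = sites$z,
                    lobe = sites$lobe, hemisphere = sites$hemisphere,
                    is_soz = as.integer(sites$is_soz),
                    is_spike_zone = as.integer(sites$is_spike_zone),
                    is_lesion = as.integer(sites$is_lesion))
  tsv_write(out, path)
}

#' @rdname read_sites
#' @export
is_nonepileptic <- function(sites) {
  !sites$is_soz & !sites$is_spike_zone & !sites$is_lesion
}

#' Read / write a subject-profiles table
#'
#' Columns: \code{subject_id, age} (years, decimal), \code{sex}
#' (female/male), \code{n_asm} (count of antiseizure medications),
#' \code{has_mri_lesion}, \code{soz_lobes} (comma-joined subset of lobes),
#' \code{sampled_hemisphere} (left/right/both).
#'
#' @param path TSV path.
#' @return data.frame of subject profiles.
#' @export
read_subjects <- function(path) {
  tab <- tsv_read(path)
  need <- c("subject_id", "age", "sex", "n_asm")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("subjects table missing column(s): ",
                             paste(miss, collapse = ", "))
  tab$age <- as.numeric(tab$age)
  if (any(!is.finite(tab$age)) || any(tab$age < 0.5 | tab$age > 100)) {
    stop("subject age outside plausible range (0.5-100 years)")
  }
  tab$n_asm <- as.integer(tab$n_asm)
  if (any(tab$n_asm < 0)) stop("n_asm must be >= 0")
  if (!"has_mri_lesion" %in% names(tab)) tab$has_mri_lesion <- FALSE
  tab$has_mri_lesion <- parse_flag(tab$has_mri_lesion)
  if (!"soz_lobes" %in% names(tab)) tab$soz_lobes <- ""
  if (!"sampled_hemisphere" %in% names(tab)) tab$sampled_hemisphere <- "left"
  tab
}

#' @rdname read_subjects
#' @param subjects a subjects data.frame.
#' @export
write_subjects <- function(subjects, path) tsv_write(subjects, path)

#' Biomarker table I/O
#'
#' A biomarker table is a data.frame with a \code{site_id} key column and one
#' numeric column per biomarker (per-band MI values and per-detector HFO
#' rates). The on-disk form is TSV with full double precision, so a
#' write-read cycle is lossless to well beyond 9 significant digits.
#'
#' @param table biomarker data.frame (first column \code{site_id}).
#' @param path TSV path.
#' @return \code{read_biomarker_table}: the table; \code{write_biomarker_table}:
#'   the path, invisibly.
#' @export
write_biomarker_table <- function(table, path) {
  if (!"site_id" %in% names(table)) stop("biomarker table needs a site_id column")
  if (anyDuplicated(table$site_id)) {
    stop("duplicate site_id in biomarker table: ",
         table$site_id[duplicated(table$site_id)][1])
  }
  tsv_write(table, path)
}

#' @rdname write_biomarker_table
#' @export
read_biomarker_table <- function(path) {
  tab <- tsv_read(path)
  if (!"site_id" %in% names(tab)) stop("biomarker table needs a site_id column")
  if (anyDuplicated(tab$site_id)) {
    stop("duplicate site_id in biomarker table: ",
         tab$site_id[duplicated(tab$site_id)][1])
  }
  tab$site_id <- as.character(tab$site_id)
  for (j in setdiff(names(tab), "site_id")) tab[[j]] <- as.numeric(tab[[j]])
  tab
}

#' Pipeline configuration defaults
#'
#' Every tunable of the pipeline with its default. Slow-wave phase bands are
#' the eight 1-Hz-wide bands 0.5-1 through 7-8 Hz; amplitude high-pass cuts
#' are 80 and 150 Hz with upper limit min(330, 0.9 x Nyquist).
#'
#' @return nested named list of parameters.
#' @export
default_config <- function() {
  list(
    fs = 1000,
    epoch_min = 20,
    bands = list(
      s_grid = list(c(0.5, 1), c(1, 2), c(2, 3), c(3, 4),
                    c(4, 5), c(5, 6), c(6, 7), c(7, 8)),
      f_cuts = c(80, 150),
      hfo_upper_hz = 330,
      trans_frac = 0.25),
    sleep = list(window_s = 30, bin_s = 1, delta_band = c(0.5, 2),
                 broad_band = c(0.5, 40), dominance = 0.5, min_fraction = 0.20),
    hfo = list(
      ste = list(rms_ms = 3, thr_sd = 5, min_dur_ms = 6, gap_ms = 10,
                 peak_sd = 3, min_peaks = 6),
      sll = list(window_ms = 80, pct = 0.975),
      hil = list(thr_sd = 5, min_dur_ms = 10, gap_ms = 10),
      mni = list(rms_ms = 10, seg_ms = 125, flatness_thr = 0.5,
                 baseline_min_s_per_min = 5, baseline_pct = 0.999999,
                 fallback_pct = 0.95, fallback_min_augment = 1.5,
                 min_dur_ms = 10, gap_ms = 10)),
    atlas = list(patch_size = 20, radius_mm = 10, q = 0.05,
                 transforms = c("age", "sqrt_age", "log10_age")),
    zscore = list(k = 30, window_years = 3.9, symmetric_window = FALSE),
    stats = list(age_split = 4.0, q = 0.05),
    tracts = list(min_fraction = 0.5, seed_radius_mm = 4),
    seed = 1L)
}

#' @rdname default_config
#' @param path YAML file of overrides (requires the yaml package).
#' @export
load_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("load_config requires the 'yaml' package")
  }
  over <- yaml::read_yaml(path)
  modifyList(default_config(), over)
}
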