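# End-to-end orchestration on a (simulated or supplied) cohort: sleep
# validation -> MI + HFO on signals -> normative atlas -> z-scores -> mixed
# models -> co-growth edges. Each stage's outputs are written as TSV; a JSON
# manifest is written last, so a complete manifest implies a complete run.

#' Run the full pipeline on a small synthetic cohort
#'
#' Demonstration/orchestration entry point: simulates a signal epoch and a
#' biomarker cohort under \code{config}, runs every stage in order, writes
#' all stage outputs into \code{out_dir}, and writes a run manifest
#' (config snapshot, package version, seed, output paths) last. Two runs
#' with the same seed and config produce identical outputs.
#'
#' @param config configuration list (see \code{\link{default_config}}).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for all randomness.
#' @param n_subjects cohort size for the demonstration run.
#' @param signal_duration seconds of simulated signal for the signal-level
#'   stages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         seed = config$seed, n_subjects = 8,
                         signal_duration = 120) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sig <- stage("simulate", {
    sp <- signal_spec(duration = signal_duration, seed = seed)
    simulate_signal(sp)
  })
  co <- stage("simulate", {
    cs <- cohort_spec(n_subjects = n_subjects,
                      age_range = c(2, 12), seed = seed)
    simulate_cohort(cs)
  })
  paths$subjects <- file.path(out_dir, "subjects.tsv")
  paths$sites <- file.path(out_dir, "electrodes.tsv")
  paths$biomarkers <- file.path(out_dir, "biomarkers.tsv")
  write_subjects(co$subjects, paths$subjects)
  write_sites(co$sites, paths$sites)
  write_biomarker_table(co$biomarkers, paths$biomarkers)

  sws <- stage("sleep", {
    validate_sws_epoch(sig$recording, epoch_min = signal_duration / 60,
                       delta_band = config$sleep$delta_band,
                       broad_band = config$sleep$broad_band,
                       dominance = config$sleep$dominance,
                       min_fraction = config$sleep$min_fraction)
  })

  mi <- stage("pac", compute_mi(sig$recording, f_cut = 80,
                                s_band = config$bands$s_grid[[1]]))
  paths$mi <- file.path(out_dir, "mi.tsv")
  tsv_write(mi, paths$mi)

  hfo_events <- stage("hfo", detect_hfo(sig$recording, "HIL", f_cut = 80,
                                        config = config$hfo))
  rates <- compute_rate(hfo_events, signal_duration / 60,
                        site_ids = sig$recording$channel_ids)
  paths$hfo <- file.path(out_dir, "hfo_rates.tsv")
  tsv_write(rates, paths$hfo)

  atl <- stage("atlas", {
    mapped <- map_sites_to_mesh(co$sites, co$biomarkers$mi80_0.5_1, co$mesh,
                                radius_mm = config$atlas$radius_mm)
    ages <- co$subjects$age[match(colnames(mapped$point_values),
                                  co$subjects$subject_id)]
    fits <- fit_atlas(mapped$point_values, ages,
                      transforms = config$atlas$transforms)
    fits
  })
  sqrt_fits <- atl[atl$transform == "sqrt_age", ]
  sig_mask <- rep(FALSE, length(co$mesh$patches))
  sel <- fdr_select(sqrt_fits$p, config$atlas$q)
  sig_mask[sqrt_fits$point[sel]] <- TRUE
  paths$atlas <- file.path(out_dir, "atlas_fits.tsv")
  tsv_write(as.data.frame(atl), paths$atlas)

  ztab <- stage("zscore", {
    zscore_table(co$biomarkers, co$sites, co$subjects,
                 measures = "mi80_0.5_1", k = config$zscore$k,
                 window = config$zscore$window_years, widen_if_short = TRUE)
  })
  paths$zscores <- file.path(out_dir, "zscores.tsv")
  tsv_write(ztab, paths$zscores)

  soz <- stage("stats", soz_deviation_test(ztab, co$sites, co$subjects,
                                           q = config$stats$q))
  paths$soz <- file.path(out_dir, "soz_tests.tsv")
  tsv_write(soz, paths$soz)

  edges <- stage("tracts", {
    slopes <- rep(0, length(co$mesh$patches))
    slopes[sqrt_fits$point] <- sqrt_fits$beta1
    sig_pts <- which(sig_mask)
    recs <- if (length(sig_pts) >= 2) {
      a <- co$mesh$patch_centers[sig_pts[1], ]
      b <- co$mesh$patch_centers[sig_pts[2], ]
      data.frame(ax = a[1], ay = a[2], az = a[3],
                 bx = b[1], by = b[2], bz = b[3],
                 tract = "corpus callosum", fraction = 1)
    } else {
      data.frame(ax = numeric(0), ay = numeric(0), az = numeric(0),
                 bx = numeric(0), by = numeric(0), bz = numeric(0),
                 tract = character(0), fraction = numeric(0))
    }
    recs <- filter_streamlines(recs, config$tracts$min_fraction)
    attach_endpoints(recs, co$mesh, slopes, sig_mask,
                     seed_radius = config$tracts$seed_radius_mm)
  })
  paths$edges <- file.path(out_dir, "cogrowth_edges.tsv")
  tsv_write(edges, paths$edges)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ieegatlas")),
    seed = seed,
    config = config,
    sws_pass = sws$pass,
    n_significant_points = sum(sig_mask),
    outputs = paths)
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
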