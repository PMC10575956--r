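# Synthetic-data generators. Two levels: (1) raw signals with slow waves and
# phase-coupled >=80 Hz bursts, for testing the signal-level stages; (2)
# biomarker-level cohorts matching a surgical cohort's statistical structure (site
# counts per lobe, sqrt(age) growth curves, SOZ shifts), for testing the
# atlas/z-score/mixed-model stages at full cohort scale without simulating
# hours of signal.

#' Specification of one synthetic iEEG signal
#'
#' The generated signal is
#' \deqn{x(t) = a_s \cos\varphi(t) + A(t)\cos(2\pi f_h t + \theta)\,g(t)
#'   + \mathrm{spikes}(t) + \varepsilon(t)}
#' where \eqn{\varphi(t)} is the phase of a narrowband Gaussian process
#' filtered to \code{slow_band} (so phase estimation downstream is
#' nontrivial), \eqn{g(t)} is a Poisson burst gate, and the burst envelope
#' \eqn{A(t) = a_h [1 - \kappa + \kappa (1 + \cos(\varphi - \phi_0))/2]}
#' carries the ground-truth phase-amplitude coupling of depth \eqn{\kappa}.
#'
#' @param duration seconds.
#' @param fs sampling rate, Hz.
#' @param slow_band slow-wave band (lo, hi) Hz.
#' @param slow_amp slow-wave amplitude, microvolts.
#' @param hfo_freq burst carrier frequency, Hz (>= 80, < fs/2).
#' @param hfo_burst_rate bursts per minute; \code{Inf} keeps the gate open
#'   for the whole signal (continuous oscillation).
#' @param hfo_burst_dur burst duration, ms.
#' @param hfo_amp burst amplitude, microvolts.
#' @param coupling_depth kappa in [0, 1]: fraction of the burst envelope
#'   modulated by slow-wave phase.
#' @param preferred_phase phase (radians) at which the envelope peaks.
#' @param spikewave_rate spike-and-wave transients per minute; each is one
#'   3.5-Hz wave cycle with a 50-ms burst locked to its trough.
#' @param noise_sd additive white-noise SD, microvolts.
#' @param seed integer seed; expanded into substreams internally.
#' @return a validated \code{signal_spec} list.
#' @export
signal_spec <- function(duration = 60, fs = 1000, slow_band = c(0.5, 1),
                        slow_amp = 50, hfo_freq = 120, hfo_burst_rate = 60,
                        hfo_burst_dur = 100, hfo_amp = 15,
                        coupling_depth = 0.6, preferred_phase = 0,
                        spikewave_rate = 0, noise_sd = 5, seed = 1L) {
  spec <- list(duration = duration, fs = fs, slow_band = slow_band,
               slow_amp = slow_amp, hfo_freq = hfo_freq,
               hfo_burst_rate = hfo_burst_rate, hfo_burst_dur = hfo_burst_dur,
               hfo_amp = hfo_amp, coupling_depth = coupling_depth,
               preferred_phase = preferred_phase,
               spikewave_rate = spikewave_rate, noise_sd = noise_sd,
               seed = as.integer(seed))
  if (spec$coupling_depth < 0 || spec$coupling_depth > 1) {
    stop("coupling_depth must lie in [0, 1]")
  }
  if (spec$hfo_freq >= fs / 2) stop("hfo_freq must be below fs/2")
  if (!is.infinite(spec$hfo_burst_rate) && spec$hfo_burst_rate < 0) {
    stop("rates must be >= 0")
  }
  if (spec$spikewave_rate < 0) stop("rates must be >= 0")
  class(spec) <- "signal_spec"
  spec
}

#' Generate one synthetic iEEG channel with ground truth
#'
#' @param spec a \code{\link{signal_spec}}.
#' @return list with \code{recording} (an \code{ieeg_recording}, 1 channel)
#'   and \code{truth}: \code{kappa}, \code{preferred_phase},
#'   \code{burst_intervals} (0-based half-open sample intervals),
#'   \code{spike_times} (s), and \code{slow_phase} (the generating phase
#'   series, radians).
#' @export
simulate_signal <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  fs <- spec$fs
  n <- round(spec$duration * fs)
  set.seed(substream_seed(spec$seed, 1L))

  # Slow-wave phase from a narrowband Gaussian process, generated with
  # padding so the retained segment is free of filter edges.
  pad <- min(n, 10L * as.integer(fs))
  w <- stats::rnorm(n + 2L * pad)
  bp <- fir_filter(w, fs, spec$slow_band[1], spec$slow_band[2])
  phi <- Arg(analytic_signal(bp$x))[(pad + 1L):(pad + n)]

  tt <- (seq_len(n) - 1) / fs
  gate <- numeric(n)
  if (is.infinite(spec$hfo_burst_rate)) {
    gate[] <- 1
    burst_intervals <- cbind(start = 0L, end = n)
  } else {
    dur_samp <- max(1L, round(spec$hfo_burst_dur / 1000 * fs))
    n_ev <- stats::rpois(1, spec$hfo_burst_rate * spec$duration / 60)
    if (n_ev > 0) {
      starts <- sort(stats::runif(n_ev, 0, spec$duration - dur_samp / fs))
      s0 <- pmin(floor(starts * fs), n - dur_samp)
      runs <- cbind(start = as.integer(s0 + 1L),
                    end = as.integer(s0 + dur_samp))
      runs <- merge_runs(runs[order(runs[, 1]), , drop = FALSE], 1L)
      for (i in seq_len(nrow(runs))) gate[runs[i, 1]:runs[i, 2]] <- 1
      burst_intervals <- cbind(start = runs[, "start"] - 1L,
                               end = runs[, "end"])
    } else {
      burst_intervals <- cbind(start = integer(0), end = integer(0))
    }
  }

  kappa <- spec$coupling_depth
  env <- spec$hfo_amp *
    (1 - kappa + kappa * (1 + cos(phi - spec$preferred_phase)) / 2)
  theta0 <- stats::runif(1, 0, 2 * pi)
  x <- spec$slow_amp * cos(phi) +
    env * cos(2 * pi * spec$hfo_freq * tt + theta0) * gate

  spike_times <- numeric(0)
  if (spec$spikewave_rate > 0) {
    f_sw <- 3.5
    half <- 1 / (2 * f_sw)
    n_sp <- stats::rpois(1, spec$spikewave_rate * spec$duration / 60)
    if (n_sp > 0) {
      spike_times <- sort(stats::runif(n_sp, half, spec$duration - half))
      for (ct in spike_times) {
        idx <- which(tt >= ct - half & tt < ct + half)
        x[idx] <- x[idx] - spec$slow_amp * cos(2 * pi * f_sw * (tt[idx] - ct))
        bidx <- which(tt >= ct - 0.025 & tt < ct + 0.025)
        x[bidx] <- x[bidx] + spec$hfo_amp *
          cos(2 * pi * spec$hfo_freq * tt[bidx])
      }
    }
  }

  x <- x + stats::rnorm(n, 0, spec$noise_sd)
  rec <- recording(matrix(x, nrow = 1), fs = fs, channel_ids = "sim01",
                   subject_id = "SIM")
  list(recording = rec,
       truth = list(kappa = kappa, preferred_phase = spec$preferred_phase,
                    burst_intervals = burst_intervals,
                    spike_times = spike_times, slow_phase = phi))
}

# ---------------------------------------------------------------------------
# Surface mesh

# Azimuthal four-sector lobe labelling shared by the mesh and the cohort
# placement, so simulated electrodes land in the lobe they claim.
lobe_sector <- function(xyz) {
  theta <- atan2(xyz[, 2], xyz[, 1])        # (-pi, pi]
  sector <- pmin(floor((theta + pi) / (pi / 2)), 3)
  c("parietal", "occipital", "frontal", "temporal")[sector + 1]
}

#' Icosphere surface mesh with lobe sectors and vertex patches
#'
#' Repeated 4-fold subdivision of an icosahedron projected to a sphere of
#' radius 100 mm; \code{10 * 4^n_subdiv + 2} vertices. Vertices are labelled
#' with one of four azimuthal "lobe" sectors and partitioned into connected
#' patches of \code{patch_size} vertices ("mesh points") by breadth-first
#' growth from farthest-point-sampled seeds. Patches are the spatial unit of
#' the normative atlas.
#'
#' @param n_subdiv number of subdivision rounds (>= 0).
#' @param patch_size vertices per mesh point (default 20).
#' @param radius sphere radius, mm.
#' @return object of class \code{surface_mesh}: list with \code{vertices}
#'   (N x 3, mm), \code{faces} (F x 3, 1-based), \code{lobe} (per vertex),
#'   \code{patches} (list of vertex-index vectors), \code{patch_lobe},
#'   \code{patch_centers} (patch centroid coordinates), and
#'   \code{patch_full} (FALSE for undersized remainder patches).
#' @export
make_sphere_mesh <- function(n_subdiv = 3, patch_size = 20, radius = 100) {
  if (n_subdiv < 0) stop("n_subdiv must be >= 0")
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  normalize <- function(m) m / sqrt(rowSums(m^2))
  v <- normalize(v)
  for (s in seq_len(n_subdiv)) {
    midpoint_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    new_vertices <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(midpoint_cache[[key]])) return(midpoint_cache[[key]])
      nv <<- nv + 1L
      new_vertices[[length(new_vertices) + 1L]] <<- (v[a, ] + v[b, ]) / 2
      midpoint_cache[[key]] <- nv
      nv
    }
    new_faces <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      new_faces[(4 * (i - 1) + 1):(4 * i), ] <-
        rbind(c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- normalize(rbind(v, do.call(rbind, new_vertices)))
    f <- new_faces
  }
  v <- v * radius

  # vertex adjacency from faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  adj <- split(edges[, 2], edges[, 1])
  adj <- lapply(adj, function(x) sort(unique(x)))

  patches <- grow_patches(v, adj, patch_size)
  centers <- t(vapply(patches, function(ix) colMeans(v[ix, , drop = FALSE]),
                      numeric(3)))
  lobe <- lobe_sector(v)
  patch_lobe <- vapply(patches, function(ix) {
    tab <- table(lobe[ix])
    names(tab)[which.max(tab)]
  }, "")
  structure(list(vertices = v, faces = f, lobe = lobe, patches = patches,
                 patch_lobe = patch_lobe, patch_centers = centers,
                 patch_full = lengths(patches) == patch_size,
                 patch_size = patch_size),
            class = "surface_mesh")
}

# Deterministic patch construction: a spiral sweep. Starting from a
# farthest-point anchor, repeatedly BFS-collect patch_size still-unassigned
# vertices; each new patch starts at the unassigned vertex closest to the
# previous patch's centroid, so the sweep stays local and leaves few
# undersized remainder patches.
grow_patches <- function(vertices, adj, patch_size) {
  n <- nrow(vertices)
  assigned <- rep(FALSE, n)
  patches <- list()
  bfs_collect <- function(start) {
    mm <- integer(0)
    queue <- start
    while (length(queue) > 0 && length(mm) < patch_size) {
      u <- queue[1]; queue <- queue[-1]
      if (assigned[u]) next
      assigned[u] <<- TRUE
      mm <- c(mm, u)
      nb <- adj[[as.character(u)]]
      queue <- c(queue, nb[!assigned[nb]])
    }
    mm
  }
  start <- 1L
  repeat {
    mm <- bfs_collect(start)
    patches[[length(patches) + 1L]] <- mm
    if (all(assigned)) break
    centroid <- colMeans(vertices[mm, , drop = FALSE])
    free <- which(!assigned)
    d <- sqrt(colSums((t(vertices[free, , drop = FALSE]) - centroid)^2))
    start <- free[which.min(d)]
  }
  patches
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, %d mesh points (patch size %d)\n",
              nrow(x$vertices), nrow(x$faces), length(x$patches), x$patch_size))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cohort generator

#' Specification of a synthetic biomarker cohort
#'
#' Per-site biomarker values are drawn as
#' \code{intercept + slope * sqrt(age) + Normal(0, noise_sd)} with lobe- and
#' biomarker-specific curves; seizure-onset-zone (SOZ) sites get an additive
#' shift. Defaults mirror a paediatric-to-adult surgical cohort: 114 subjects aged
#' 1.0-41.5 years (log-uniform), about 73 nonepileptic sites per subject
#' split 26/21/18/8 across frontal/temporal/parietal/occipital, 9 SOZ sites
#' in one SOZ lobe per subject, MI growth steepest in the occipital lobe
#' (+0.047 per sqrt-year) and HFO-rate decline outside it.
#'
#' @param n_subjects number of subjects.
#' @param age_range (lo, hi) years; ages are log-uniform in this range.
#' @param sites_per_lobe named integer vector of nonepileptic sites per lobe.
#' @param n_soz SOZ sites per subject (placed in that subject's SOZ lobe).
#' @param curves data.frame with columns \code{biomarker, lobe, intercept,
#'   slope, noise_sd}; the growth curve is in sqrt(age) units.
#' @param soz_shift named numeric: additive SOZ shift per biomarker.
#' @param seed integer seed.
#' @return a validated \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_subjects = 114, age_range = c(1.0, 41.5),
                        sites_per_lobe = c(frontal = 26, temporal = 21,
                                           parietal = 18, occipital = 8),
                        n_soz = 9, curves = default_cohort_curves(),
                        soz_shift = c(mi80_0.5_1 = 0.15, rate_hil80 = 1.5),
                        seed = 1L) {
  stopifnot(all(c("biomarker", "lobe", "intercept", "slope", "noise_sd") %in%
                  names(curves)))
  if (any(age_range < 0.5)) stop("ages must be >= 0.5 years")
  # curve values must stay in range over the whole age span
  for (i in seq_len(nrow(curves))) {
    vals <- curves$intercept[i] + curves$slope[i] * sqrt(age_range)
    if (startsWith(curves$biomarker[i], "mi") && any(vals < 0 | vals > 1)) {
      stop("MI curve leaves [0,1] over the age range: ", curves$biomarker[i])
    }
    if (startsWith(curves$biomarker[i], "rate") && any(vals < 0)) {
      stop("rate curve goes negative over the age range: ", curves$biomarker[i])
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 sites_per_lobe = sites_per_lobe, n_soz = as.integer(n_soz),
                 curves = curves, soz_shift = soz_shift,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cohort_curves <- function() {
  lobes <- c("frontal", "temporal", "parietal", "occipital")
  rbind(
    data.frame(biomarker = "mi80_0.5_1", lobe = lobes,
               intercept = 0.05,
               slope = c(0.0070, 0.0072, 0.011, 0.047),
               noise_sd = 0.05),
    data.frame(biomarker = "rate_hil80", lobe = lobes,
               intercept = c(3.5, 2.6, 2.9, 1.0),
               slope = c(-0.41, -0.30, -0.33, 0.081),
               noise_sd = 0.8))
}

#' Simulate a biomarker-level cohort
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param mesh a \code{surface_mesh} on which electrodes are placed (default:
#'   3-fold subdivided icosphere). Each site takes a random mesh vertex of
#'   its lobe plus 2-mm jitter.
#' @return list with \code{subjects}, \code{sites}, \code{biomarkers} (a
#'   biomarker table, one column per biomarker), \code{mesh}, and
#'   \code{truth} (curves, SOZ shifts, per-site noiseless values).
#' @export
simulate_cohort <- function(spec, mesh = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(mesh)) mesh <- make_sphere_mesh(3)
  set.seed(substream_seed(spec$seed, 2L))
  ns <- spec$n_subjects
  ages <- exp(stats::runif(ns, log(spec$age_range[1]), log(spec$age_range[2])))
  lobes <- names(spec$sites_per_lobe)
  subjects <- data.frame(
    subject_id = sprintf("sub%03d", seq_len(ns)),
    age = ages,
    sex = sample(c("female", "male"), ns, replace = TRUE),
    n_asm = stats::rpois(ns, 2),
    has_mri_lesion = stats::runif(ns) < 0.5,
    soz_lobes = sample(lobes, ns, replace = TRUE),
    sampled_hemisphere = sample(c("left", "right"), ns, replace = TRUE),
    stringsAsFactors = FALSE)

  vert_by_lobe <- split(seq_len(nrow(mesh$vertices)), mesh$lobe)
  site_rows <- vector("list", ns)
  for (i in seq_len(ns)) {
    lobe_vec <- rep(lobes, times = spec$sites_per_lobe)
    soz_flag <- rep(FALSE, length(lobe_vec))
    if (spec$n_soz > 0) {
      lobe_vec <- c(lobe_vec, rep(subjects$soz_lobes[i], spec$n_soz))
      soz_flag <- c(soz_flag, rep(TRUE, spec$n_soz))
    }
    vidx <- vapply(lobe_vec, function(lb) sample(vert_by_lobe[[lb]], 1), 0L)
    xyz <- mesh$vertices[vidx, , drop = FALSE] +
      matrix(stats::rnorm(3 * length(vidx), 0, 2), ncol = 3)
    site_rows[[i]] <- data.frame(
      site_id = sprintf("%s_e%03d", subjects$subject_id[i],
                        seq_along(lobe_vec)),
      subject_id = subjects$subject_id[i],
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      lobe = lobe_vec,
      hemisphere = subjects$sampled_hemisphere[i],
      is_soz = soz_flag, is_spike_zone = FALSE, is_lesion = FALSE,
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL

  age_by_site <- subjects$age[match(sites$subject_id, subjects$subject_id)]
  biomarkers <- data.frame(site_id = sites$site_id, stringsAsFactors = FALSE)
  truth_values <- list()
  for (bm in unique(spec$curves$biomarker)) {
    cc <- spec$curves[spec$curves$biomarker == bm, ]
    mu <- cc$intercept[match(sites$lobe, cc$lobe)] +
      cc$slope[match(sites$lobe, cc$lobe)] * sqrt(age_by_site)
    sd_bm <- cc$noise_sd[match(sites$lobe, cc$lobe)]
    vals <- mu + stats::rnorm(nrow(sites), 0, sd_bm)
    shift <- if (bm %in% names(spec$soz_shift)) spec$soz_shift[[bm]] else 0
    vals[sites$is_soz] <- vals[sites$is_soz] + shift
    if (startsWith(bm, "rate")) {
      neg <- vals < 0
      if (any(neg)) {
        warning(sum(neg), " negative ", bm, " value(s) clipped at 0")
        vals[neg] <- 0
      }
    }
    biomarkers[[bm]] <- vals
    truth_values[[bm]] <- mu
  }
  list(subjects = subjects, sites = sites, biomarkers = biomarkers,
       mesh = mesh,
       truth = list(curves = spec$curves, soz_shift = spec$soz_shift,
                    noiseless = truth_values))
}
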