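---
title: "Methods: normative developmental atlases of sleep iEEG biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative developmental atlases of sleep iEEG biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegatlas)
```

## The scientific problem

Intracranial EEG (iEEG) biomarkers of epileptogenic cortex — the
phase-amplitude modulation index (MI) and the rate of high-frequency
oscillations (HFOs) — are also shaped by normal brain development. A site in
a three-year-old's occipital cortex can produce physiological HFO rates and
delta-nested coupling that would look pathological in an adult's frontal
lobe. `ieegatlas` implements the full analysis chain needed to separate the
two: it characterises the normal developmental trajectory of each biomarker
across the cortical surface from nonepileptic electrode sites, and then
scores individual sites — in particular seizure-onset-zone (SOZ) candidates
— by how far they deviate from the age- and location-matched norm.

The pipeline has seven analysis stages, each exposed as ordinary functions:
slow-wave-sleep epoch validation (`validate_sws_epoch`, `rayleigh_test`),
the modulation index (`compute_mi`, `mi_band_profile`), four HFO detectors
(`detect_hfo`), surface-mesh atlas regression (`map_sites_to_mesh`,
`fit_atlas`, `predict_atlas`, `fdr_select`), normative z-scoring
(`normative_reference`, `zscore`, `zscore_table`), mixed-effects group
inference (`fit_mixed`, `soz_deviation_test`, `occipital_enhancement`), and
white-matter co-growth (`filter_streamlines`, `attach_endpoints`). A
synthetic generator (`simulate_signal`, `simulate_cohort`,
`make_sphere_mesh`) produces data with the statistical structure every stage
assumes, so the whole chain is testable without patient recordings.

## Slow-wave-sleep validation

The inclusion rule for an analysable 20-minute epoch is that low-frequency
(< 2 Hz) activity dominates at least 20% of the time in every 30-s window.
Visual scoring cannot be automated exactly, so the package operationalises
it as a per-second power criterion: within each 1-s bin (Welch periodogram,
1-s windows, no overlap) a channel is "delta-dominant" when 0.5–2 Hz power
is at least 50% of 0.5–40 Hz power. The per-window fraction of
delta-dominant bins is the median across nonepileptic channels, and the
epoch passes iff every window reaches 0.20 (boundary inclusive). Because the
criterion is a power *ratio*, it is invariant to channel amplitude scaling.
The median-across-channels rule is a package choice; the source analysis
protocol does not specify the cross-channel aggregation.

Epoch onset clock times are tested for circular uniformity with Rayleigh's
test (angles `2*pi*hour/24`; `z = n * Rbar^2`, p from Zar's approximation)
and for age dependence with a tie-corrected Spearman correlation.

## Modulation index

For a high-pass cut `f` (80 or 150 Hz) and slow-wave band `s`, the signal is
zero-phase filtered twice: a band-pass at `s` whose analytic-signal angle
gives the slow-wave phase `phi(t)` (phase 0 at the waveform's positive
peak), and a high-pass at `f` (upper limit `min(330, 0.9 * Nyquist)` Hz)
whose analytic-signal magnitude gives the amplitude envelope `A(t)`. The
modulation index is the amplitude-normalised mean vector length

$$\mathrm{MI} = \frac{\left|\sum_t A(t) e^{i\varphi(t)}\right|}{\sum_t A(t)} \in [0, 1].$$

The normalisation is a deliberate package choice: the raw mean-vector-length
measure carries signal units, whereas the normalised form is scale-free and
admits exact invariants (`MI` unchanged under `x -> c*x`; closed form
`MI = 1/2` for `A = 1 + cos(phi)`; `MI -> 1` for perfectly phase-locked
bursts). The raw variant remains available (`normalize = FALSE`). Because
the upstream tool's internal normalisation is not documented, absolute MI
values may differ from published ones by a monotone rescaling; slopes and
contrasts are unaffected in direction.

One MI value is computed per channel over the whole epoch (no
sub-windowing), with one filter length excluded at each edge, and is
reported only when at least 10 slow-wave cycles remain.

**Filters.** All filters are linear-phase Hamming-window FIR designs
(`signal::fir1`) applied forward-backward (implemented as a single
convolution with the filter's autocorrelation, which is exactly zero-phase).
The design rule is a transition width of 25% of the lower band edge; at
1000 Hz and a 0.5 Hz edge that implies ~26,000 taps, which a 20-minute epoch
accommodates comfortably. For shorter signals the order is capped at
`floor(n/6)` taps so a usable interior always remains; the cap widens the
transition band but preserves zero phase and unit passband gain.

**Band grid.** The slow-wave grid is the eight 1-Hz-wide bands 0.5–1 …
7–8 Hz. `mi_band_profile` fits an ordinary least-squares slope of MI against
band centre frequency (units /Hz) per channel; lobe-level summaries average
over channels, and `band_slope_age_dependence` tests the Spearman
correlation of the per-subject lobe mean with age, Benjamini–Hochberg over
the four lobes.

## HFO detectors

All four detectors operate on the `f`-Hz high-passed trace with thresholds
that are relative statistics of that same trace, so every detector is
invariant to amplitude scaling. The published rules fix the headline
thresholds; window lengths, minimum durations and merge gaps below are
package defaults (all configurable via `default_config()$hfo`):

* **STE** — 3-ms moving RMS; candidates are runs above mean + 5 SD lasting
  ≥ 6 ms, merged when < 10 ms apart; kept only when the rectified trace has
  *more than six* peaks above mean + 3 SD (strictly exclusive: six peaks are
  rejected).
* **SLL** — line length summed over a sliding 80-ms window; candidates
  exceed the epoch ECDF's 97.5th percentile and span at least one window.
* **HIL** — analytic envelope above mean + 5 SD for ≥ 10 ms, gaps < 10 ms
  merged. This is the headline detector at 80 Hz.
* **MNI** — 10-ms RMS energy against a baseline formed from 125-ms segments
  whose spectral flatness (Wiener entropy, 80–450 Hz) exceeds 0.5. When
  baseline covers ≥ 5 s per minute, the threshold is the 99.9999th
  percentile of a moment-fit Gamma distribution of baseline RMS; otherwise a
  per-minute iterative 95th-ECDF-percentile threshold applies, and a
  detection must additionally reach 1.5× the segment's median RMS. That
  augmentation ratio is a package default: it encodes the detector's design
  intent of being agnostic to *persistent* high-frequency activity — a
  constant-amplitude carrier produces (nearly) no events while the same
  carrier gated at 10% duty cycle is detected burst by burst.

The flatness threshold of 0.5 reflects that high-pass filtering shapes the
in-band spectrum: white-noise segments sit near 0.6–0.8 rather than 1.
Event indices are 0-based and half-open; rates are events/minute over the
epoch.

## Normative atlas

Electrode values are projected onto a triangulated surface: every vertex
within 10 mm (Euclidean, inclusive) of a subject's electrode takes the mean
of that subject's covering electrodes; a *mesh point* — a connected patch of
20 vertices — takes the mean of its covered vertices. Each subject thus
contributes at most one value per mesh point, preventing pseudo-replication;
lobe-level analyses on per-electrode values (matching the printed
degrees-of-freedom style of cohort tables) are also supported via
`fit_development` on electrode vectors.

The patch partition is deterministic: farthest-point-anchored spiral sweep,
each patch collected by breadth-first search over still-unassigned vertices.
A few remainder patches may hold fewer than 20 vertices and are flagged
(`patch_full`). On the synthetic icosphere (subdivision 3: 642 vertices)
this yields 33–36 patches.

Per mesh point and per age transform (age, √age, log₁₀ age) the package
fits ordinary least squares with `t = slope/SE` on `n − 2` degrees of
freedom and AIC under the full Gaussian likelihood; transforms are compared
by AIC. Significance masks use Benjamini–Hochberg FDR at q = 0.05 over the
family the caller states (the developmental scans use 18 = six measures ×
three transforms). Predicted atlases at age `a` are `b0 + b1·T(a)` (mean)
or plus `2·sigma` (upper normative band); ages outside the fitted range are
allowed but flagged.

## z-score deviation

A site's reference is the 30 spatially nearest nonepileptic sites of
*other* subjects whose age lies in the forward window `[n, n + 3.9]` years
(n = the query subject's age) — implemented exactly as printed, with a
symmetric-window option and an optional symmetric widening fallback when
fewer than 30 sites are eligible. Ties in distance break by site id.
`z = (raw − mean)/SD` with the n−1 SD; a zero reference SD flags z as
undefined. Leave-one-out calibration on a homogeneous synthetic cohort gives
mean ≈ 0 and SD ≈ 1.03 (the small excess is the `E[sigma/s]` inflation of a
30-site reference).

## Mixed-effects inference

All group-level models are linear mixed models with a per-patient random
intercept, fitted by maximum likelihood with lme4 — the solver is
deliberately an off-the-shelf component; the package's contract is the model
specification, the covariate coding (female = 1, SOZ = 1, lesion = 1,
left = 1), the residual-DF convention (`DF = n_obs − n_fixed`, matching the
printed-table style; Satterthwaite is deliberately not used), and the FDR
bookkeeping (six measures for the SOZ and occipital families, four lobes for
the band-slope family). `fit_mixed(..., constrain_zero_ranef = TRUE)` pins
the random-intercept variance at zero, in which case the model reduces
exactly to OLS — the basis of an oracle equivalence test. The developmental
model is `value ~ 1 + age + sex + SOZ + MRI + hemisphere + n_asm +
(1 | patient)`; the SOZ deviation model is `z ~ 1 + SOZ + (1 | patient)` per
lobe (SOZ label only by default; the full-covariate variant is available
through `fit_mixed` directly). The neuropsychological-score association is
the same machinery with the test score as outcome and z-scored occipital MI
as predictor; no bespoke code exists for it.

## The synthetic generator: what it emulates, and what it does not

`simulate_signal` builds `x(t) = slow_amp·cos(phi) + A(t)·carrier·gate +
spikes + noise`, where `phi` is the phase of a narrowband Gaussian process
filtered to the slow band — not a pure sinusoid, so downstream phase
estimation is nontrivial — and `A(t) = hfo_amp·[1 − κ + κ(1 +
cos(phi − phi0))/2]` carries a controllable coupling depth κ as ground
truth. Bursts are Poisson-gated (rate in events/min; `Inf` = continuous);
spike-and-wave transients are one 3.5-Hz wave cycle with a 50-ms burst
locked to the trough. One global seed expands into per-call substreams via a
counter-based mixing function, so replicates are individually reproducible.

`simulate_cohort` draws biomarker values directly (no signals):
`intercept + slope·√age + N(0, sd)` per lobe, SOZ sites shifted additively,
negative rates clipped at zero with a warning. The defaults are the study's
structure: 114 subjects, ages log-uniform on 1.0–41.5 years, nonepileptic
sites split 26/21/18/8 across frontal/temporal/parietal/occipital (≈73 per
subject, matching the printed per-lobe degrees of freedom), 9 SOZ sites in
one SOZ lobe per subject, MI growth steepest occipitally (+0.047/√year,
intercept 0.05, residual SD 0.05) and HFO-rate decline extra-occipitally
(−0.41/−0.30/−0.33/+0.081 per √year). Electrodes sit on a 100-mm icosphere
whose four azimuthal sectors stand in for lobes.

What the generator does **not** emulate: 1/f spectral background beyond
white noise, artefacts, non-Gaussian biomarker tails, spatial correlation of
biomarker values within a lobe, and real cortical geometry. Passing tests
therefore demonstrate the correctness and calibration of the *methods* under
their stated assumptions, not clinical performance on patient data.

## Problem sizes and numerical choices in the test suite

The shipped tests exercise the pipeline at sizes chosen to make Monte-Carlo
statements sharp while keeping the suite quick to run: 60-s signals for MI
nulls and monotonicity (100 and 110 signals), ten 5-minute benchmarks with
50 injected bursts each for detector recall/precision, 200 simulated
cohorts for slope-recovery coverage, null-FDR and AIC selection, a
1000-site cohort for leave-one-out z calibration, and 200 replicates of a
20-patient cohort for the SOZ mixed-model contrast. Degenerate inputs are
handled explicitly: constant outcomes give slope 0 with p = 1; an all-zero
envelope flags MI undefined; a zero reference SD flags z undefined; a
constant transformed age and singular fixed-effect designs are errors that
name the offending column.

## Known limitations

* **MI absolute scale.** The amplitude-normalised MI is a monotone
  rescaling of the raw mean-vector-length measure; absolute values are not
  comparable across normalisation conventions, only signs and orderings of
  slopes and contrasts are.
* **Full-pipeline SOZ coverage.** When an SOZ effect is injected as a *raw*
  biomarker shift and propagated through `zscore_table`, the mixed-model CI
  for the z-scale contrast undercovers (≈87% rather than 95% in our
  replications) for two structural reasons: the z-score against a 30-site
  reference is inflated by `E[sigma/s] ≈ 1 + 3/(4·29) ≈ 2.6%`, and sites
  sharing reference members have correlated z errors that a per-patient
  random intercept cannot absorb. The calibration suite therefore verifies
  CI coverage on cohorts generated with the z-shift itself (where coverage
  is nominal) and verifies the full pipeline on the direction and ordering
  of the SOZ contrast, which are robust.
* **Geodesic vs Euclidean.** Both the 10-mm interpolation radius and the
  nearest-30 search use Euclidean distance; on folded cortex a geodesic
  variant could assemble different neighbourhoods.
* **MNI fidelity.** The baseline-entropy threshold, segment lengths and the
  fallback augmentation ratio are declared package defaults consistent with
  the published descriptions, not binary-level reproductions of any
  particular toolbox.
* **≥150 Hz biomarkers.** Supported throughout, but sparse at 1000 Hz
  sampling; regression fits on ≥150 Hz HFO rates are expected to be
  unstable, mirroring the source analyses.
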