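Package: ieegatlas
Title: Normative Developmental Atlases of Intracranial EEG Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for sleep intracranial EEG
    biomarkers of cortical development. Validates slow-wave-sleep epochs,
    computes the phase-amplitude modulation index (MI) between high-frequency
    oscillation (HFO) amplitude and slow-wave phase, detects HFO events with
    four threshold algorithms (short-time energy, short line length, Hilbert
    envelope, and the Montreal Neurological Institute method), builds
    normative developmental atlases on a cortical surface mesh with
    age-transform regression and false-discovery-rate control, scores
    seizure-onset-zone sites as z-score deviations from an age-windowed
    nearest-neighbour normative reference, fits the group-level mixed-effects
    models, and computes white-matter co-growth intensities over streamline
    endpoint tables. Includes a synthetic signal and cohort generator that
    emulates the statistical structure of a paediatric-to-adult epilepsy
    surgery cohort so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    lme4,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
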