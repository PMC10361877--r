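Package: auxdose
Title: Immobilization-Device Dosimetry for Synthetic-CT Brain Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for studying how immobilization devices
    (thermoplastic mask, mask holder, flat tabletop) affect dose calculation in
    synthetic-CT-based, MRI-only brain radiotherapy planning. Provides a
    seeded head-phantom generator producing paired reference-CT, synthetic-CT
    and pseudo-MR volumes with ground-truth structures; a voxel-based
    auxiliary structure template with MR-visible marker detection and rigid
    (Kabsch) placement; Hounsfield-unit to mass-density conversion with ROI
    density overrides; a simplified parallel-beam photon dose engine with
    Siddon radiological depth and a build-up/exponential depth-dose model; and
    DVH-based evaluation statistics (D50, percent D50 deviation, beam-entrance
    distances, depth-gradient fits, opposing-beam sums) together with the
    mask-parameter sweep, static-field and template-misplacement studies built
    on them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
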