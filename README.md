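# auxdose

Immobilization devices — the thermoplastic mask, the mask holder, and the
flat tabletop — attenuate treatment beams in brain radiotherapy, but they
are invisible in MR images and therefore missing from the synthetic CT
(sCT) that an MRI-only workflow uses for dose calculation. `auxdose` is a
desk-scale R pipeline for studying that problem: it models the devices as a
voxel-based **auxiliary structure template (AST)** placed via MR-visible
markers, models the mask as a density-assigned shell around the head
contour, and quantifies the dosimetric consequences of modeling choices
with a simplified photon dose engine and DVH statistics.

It is aimed at medical-physics researchers who want a fully synthetic,
seeded, end-to-end testbed for sCT device-modeling protocols — every input
is generated by code, so every number is reproducible from one integer seed.

## What is inside

* **Phantom generator** — paired volumes per synthetic patient: a reference
  CT with devices physically present, an sCT with devices absent and
  perturbed anatomy (class-wise HU bias + noise + smoothing), and a
  pseudo-MR showing only the head and four silicone markers
  (Ø3 × 5 mm) embedded in the mask holder.
* **AST module** — template definition (holder 1.2/1.0 g/cm³, table
  1.7/0.11 g/cm³, four Ø5 mm marker ROIs), marker detection in the
  level/width = 100/200 display band, least-squares rigid (Kabsch)
  placement, single-resample voxelization, and a sequential-vs-composed
  resampling report demonstrating why placement transforms are composed
  before voxelization.
* **Mask model** — external-contour extraction, the ROI-algebra shell
  `(external + d) − external`, and prioritized density overrides on top of
  a piecewise-linear HU ↔ mass-density LUT.
* **Dose engine** — parallel rectangular fields, exact Siddon radiological
  depth, build-up × exponential depth dose
  `pdd(d) = N (1 − e^{−βd}) e^{−μd}` (μ = 0.005 mm⁻¹, β = 0.25 mm⁻¹).
* **Evaluation** — D50 (interpolated median voxel dose), the percent
  deviation ΔD50[%] between reference and recalculated dose, the
  PTV-centroid-to-beam-entrance distance D_PTV, OLS depth-gradient fits,
  opposing-beam sums, and cohort summaries.
* **Three studies** (`analysis/01…05_*.R` are thin drivers over the
  package functions): the mask-parameter sweep (d ∈ {2.5, 3} mm ×
  ρ ∈ {1.1, 1.15, 1.2} g/cm³ plus no-mask), the eight-angle static-field
  test with sixteen Ø2 cm artificial PTVs, and the template-misplacement
  study on the oblique beams.

## Worked example

```r
library(auxdose)

case <- generate_phantom(phantom_params(seed = 1))   # one synthetic patient
det  <- detect_markers(case$mr, external = case$structures$external)
fit  <- fit_rigid(case$template$marker_points, det)
cat(sprintf("placement: |t| = %.2f mm, rot = %.3f deg, rms = %.2f mm\n",
            sqrt(sum(fit$translation^2)), rotation_angle_deg(fit$rotation),
            attr(fit, "rms_mm")))

# reference arm: devices in HU; evaluated arm: sCT + placed template,
# with and without the mask shell
lut  <- default_hu_lut()
ref  <- compose_density_map(case$ct, lut)
sct  <- case$ct_anatomy                       # unperturbed anatomy here
ext  <- extract_external(sct)
plc  <- place_template(case$template, fit, vol_grid(sct))
shell <- build_mask_shell(ext, mask_spec(3, 1.2))
with_mask <- compose_density_map(sct, lut, c(unname(plc$overrides),
             list(density_override(shell, 1.2, 3))))
no_mask   <- compose_density_map(sct, lut, unname(plc$overrides))

beam <- beam_spec(90, c(5, 5), mu = 1000, isocenter = case$isocenter)
ptv  <- place_artificial_ptvs(case)$rois[["ptv_sf1_+0.2"]]
d50_of <- function(dens) d50(compute_dvh(compute_dose(dens, beam), ptv))
r <- d50_of(ref)
cat(sprintf("D50 ref %.3f Gy | mask modeled %+.3f%% | no mask %+.3f%%\n",
    r, delta_d50_pct(r, d50_of(with_mask)), delta_d50_pct(r, d50_of(no_mask))))
```

prints

```
placement: |t| = 0.25 mm, rot = 0.004 deg, rms = 0.35 mm
D50 ref 7.975 Gy | mask modeled +0.000% | no mask +1.819%
```

Reading: the marker-based placement recovers the device pose to a fraction
of the 1.5 mm voxel; with the mask modeled at its true parameters the
recalculated D50 of a lateral-beam PTV is exact, while omitting the mask
overestimates it by ≈1.8% — the attenuation of the missing 3.6 mm
water-equivalent shell.

The three study drivers write their tables under `results/`:

```sh
Rscript analysis/01_phantom_cohort.R      # volumes + marker placement check
Rscript analysis/02_mask_sweep.R          # sweep optimum, no-mask penalty
Rscript analysis/03_static_fields.R       # depth gradients + opposing sums
Rscript analysis/04_ast_misplacement.R    # misplacement penalty / recovery
Rscript analysis/05_interpolation_caution.R
```

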