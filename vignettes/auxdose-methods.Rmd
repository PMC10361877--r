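---
title: "Modeling immobilization devices in synthetic-CT brain radiotherapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling immobilization devices in synthetic-CT brain radiotherapy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In an MRI-only brain radiotherapy workflow, a synthetic CT (sCT) generated
from the planning MRI replaces the real CT for dose calculation. The patient
is scanned in the treatment setup — a thermoplastic mask molded to the head,
a mask holder, and a flat tabletop — and these devices attenuate the beam
from many gantry angles. They are, however, invisible in MR images and hence
absent from the raw sCT. Ignoring them biases the recalculated dose; an
MRI-only workflow therefore has to put the devices back.

`auxdose` implements, at desk scale, a complete workflow for doing so, plus
the dosimetric evaluation protocol that quantifies what each device
contributes:

1. a **voxel-based auxiliary structure template (AST)** describing the mask
   holder (two materials, 1.2 and 1.0 g/cm³) and the tabletop (1.7 g/cm³
   shell over 0.11 g/cm³ foam core), with four Ø5 mm marker ROIs centered on
   the positions of MR-visible silicone markers (Ø3 × 5 mm cylinders)
   embedded in the holder;
2. **marker detection** in the (pseudo-)MR volume and a **rigid (Kabsch)
   fit** that places the template in patient coordinates;
3. a simplified **mask model**: ROI algebra `(external + d) − external`
   builds a uniform shell of thickness `d` around the head contour,
   assigned a density ρ;
4. a **density-override pipeline** that converts HU to mass density through
   a piecewise-linear LUT and writes the placed structures in by priority;
5. a **parallel-beam photon dose engine** (Siddon radiological depth,
   build-up × exponential depth dose) and **DVH statistics**: D50, the
   percent deviation ΔD50\[%\] between reference and recalculated dose, the
   centroid-to-entrance distance D~PTV~, depth-gradient fits, and
   opposing-beam sums.

Because no patient data are used, a seeded **phantom generator** supplies the
cohort: for each synthetic patient it emits a reference CT with all devices
physically present, an sCT with devices absent and perturbed anatomy, and a
pseudo-MR showing only the head and the markers.

## The phantom and what it does (and does not) emulate

The head is a three-layer ellipsoid — scalp (soft tissue, 30 HU), skull
shell (700 HU, 6 mm), brain (40 HU) — with semi-axes sampled per phantom
uniformly within ±10% of (70, 90, 80) mm, mirroring the anatomical spread of
a ten-patient cohort. The molded mask is the ground-truth shell
`(external + 3 mm) − external` at 1.2 g/cm³; the sweep study treats this
(d = 3 mm, ρ = 1.2 g/cm³) as the recoverable truth. The grid is 1.5 mm
isotropic, the resolution of the planning MR sequence being emulated.

Devices in the reference CT are voxelized by placing the template at
identity, and their HU values are written through the *inverse* of the same
LUT used for dose calculation. Two consequences are intentional:

* HU → density → HU round trips exactly, so LUT choice cancels from every
  contrast (both arms always use the same LUT);
* when the sCT arm is given unperturbed anatomy, exact placement and the
  true mask parameters, both arms produce *identical* density maps — the
  perfect-modeling null in the test suite, which isolates every later
  deviation as a modeled error source, not a pipeline artifact.

The sCT perturbation is a class-wise HU bias (defaults +5 HU soft tissue,
−20 HU bone), Gaussian voxel noise (σ = 10 HU), and 3 mm FWHM smoothing,
with air outside the head left untouched. These magnitudes are free
parameters, not claims about any particular sCT algorithm. The pseudo-MR
uses arbitrary display units placed so that the markers (150) fall inside
the level/width = 100/200 band while air (−200) and soft tissue (400) fall
outside it; marker detection is therefore a band threshold, connected-
component labeling, and a volume filter around the nominal cylinder volume
(±50%, with floor/ceiling voxel-count bounds so discretization cannot
reject a true marker).

Not emulated: real MR physics and sCT synthesis, the nose mold and fixation
toggles of the real mask (the mask is deliberately a uniform shell), eye
prosthetics, intrafraction motion, and divergent beams with scatter. Passing
tests therefore demonstrate the internal consistency and sensitivity
structure of the workflow — which error sources matter, in which beam
directions, and how they cancel — not clinical dose accuracy.

## Device geometry

The holder/table stack sits posterior of the head (holder board at
y ∈ \[−116, −104\] mm, backing to −128 mm; table shell to −132 mm, foam core
to −162 mm) and spans ±120 mm laterally. The lateral width matters: the
oblique 45° beams must traverse mask + holder + table, as they do with a
real (≈500 mm wide) couch; narrower desk-scale slabs would let the oblique
central axes miss the devices entirely. The four markers sit near the
corners of the holder board (±70 mm lateral, 115 mm longitudinal spread, one
marker 3 mm deeper so the set is non-coplanar).

## The dose engine

The engine is a deliberately minimal stand-in for a clinical TPS, sufficient
for the protocol's *contrasts* (same engine on both arms):

* **Geometry**: parallel rectangular fields, hard aperture edge, no
  inverse-square factor, no scatter or penumbra. Gantry 0° enters anterior,
  90° from the patient's left, 180° through the table.
* **Depth dose**: `pdd(d) = N (1 − e^{−βd}) e^{−μd}` with μ = 0.005 mm⁻¹,
  β = 0.25 mm⁻¹ (d_max ≈ 15.6 mm, 6-MV-like), k_cal = 0.01 Gy/MU at d_max.
* **Radiological depth** is accumulated along beam-aligned rays sampled at a
  quarter of the grid spacing, from the interpolated crossing of the 0.2
  g/cm³ entrance surface, with trapezoidal correction; the exact
  single-ray Siddon traversal backs the entrance-distance computation and is
  verified against a brute-force dense-sampling oracle.
* D50 is the interpolated median of the ROI's voxel doses — voxel-exact
  order statistics, no DVH binning.

All engine constants are conventions, not claims; every evaluation compares
two doses computed with identical settings, so only the *density maps*
differ between arms.

## The three studies

**Mask sweep.** Seven configurations (no mask; d ∈ {2.5, 3} mm ×
ρ ∈ {1.1, 1.15, 1.2} g/cm³) are modeled in the sCT arm while the reference
arm carries the true mask; the per-PTV ΔD50 of a four-field cardinal
pseudo-plan (5 × 5 cm, 1000 MU each — a desk-scale stand-in for an arc-like
clinical plan) is summarized per configuration. The sweep runs on
*unperturbed* anatomy: its purpose is to isolate device-modeling error, and
the adjacent density configurations differ by only ≈0.075% in ΔD50, which a
class-bias anatomy offset of ≈0.15% would mask. Anatomy HU error is a
separate knob, exercised by the depth-gradient study. Omitting the mask
overestimates the recalculated dose by ≈1.8% on average — the attenuation
equivalent of the missing 3.6 mm water-equivalent shell — and the minimum
deviation occurs at the truth configuration by construction.

**Static-field test.** Eight beams (5 × 5 cm at 0/90/180/270°, 10 × 10 cm at
45/135/225/315°, 1000 MU) aimed at sixteen Ø2 cm PTVs, four per opposing-
beam axis at fractions ±0.2 and ±0.6 of the brain extent. Under a −2%
systematic sCT density error (applied to the LUT output of the anatomy, not
the device overrides), each single beam shows a positive depth gradient of
ΔD50 vs D~PTV~ of ≈0.01%/mm — first-order, the bias times the effective
attenuation coefficient, 0.02 × 0.005 mm⁻¹ = 10⁻⁴ per mm. Opposing-beam
sums traverse a near-constant total path, so their gradients collapse by
1–2 orders of magnitude: the arc-robustness argument in quantitative form.
D~PTV~ is measured on an anatomy + mask density (devices excluded), so the
distance is from the skin or mask surface even for posterior beams.

**Misplacement study.** The oblique 135°/225° beams are recalculated with
the template placed exactly versus rotated 1.5° (the order of the rotational
setup differences reported between imaging sessions) and shifted 2 mm
laterally, on otherwise unperturbed anatomy. Repositioning to the exact pose
recovers the full misplacement penalty — positive for every phantom. The
desk-scale magnitude is larger than clinical experience because the
synthetic holder/table have hard lateral edges near the oblique PTV rays;
the study's claim is the sign and the mechanism, not the magnitude.

## Numerical choices and conventions

* **Coordinates**: supine head-first; +x patient-left, +y anterior,
  +z superior; mm everywhere; voxel value at the voxel center; volumes are
  axis-aligned (no oblique grids).
* **Margin expansion** uses an exact Euclidean distance transform on voxel
  centers (anisotropy-aware), because the mask thickness is a metric
  quantity. The discrete metric carries a sub-voxel (~0.4 mm) surface bias:
  on a 3 mm shell that is ~15% of the shell volume, on the enclosed volume
  <2%. Both arms build the shell identically, so dose contrasts are
  unaffected.
* **Resampling**: density volumes trilinear, label masks nearest-neighbor;
  placement transforms are composed analytically and voxelized in a single
  resampling from the template's 1 mm source grid. Fill values: −1000 HU,
  otherwise 0.
* **Marker correspondence** is by canonical (z, y, x) order; if the fit
  residual exceeds 3 mm, all 24 assignments are tried and the best kept.
  The Kabsch solution uses the determinant correction, so a
  reflection-optimal case returns the best proper rotation. With 0.3 mm
  marker noise the four-marker geometry has a noise floor of ≈0.2 mm /
  ≈0.2° (mean over repeats); recovery statements in the tests are therefore
  asserted on mean errors, whose 0.5 mm / 0.5° bounds sit well above the
  floor, while per-trial residuals stay below 1 mm.
* **Interpolation caution**: the sequential-vs-composed retention report
  resamples masks by trilinear interpolation thresholded at 0.5
  (partial-volume resampling, as a TPS voxel volume experiences), because
  nearest-neighbor resampling has no systematic volume loss and cannot
  exhibit the erosion the report is meant to demonstrate; a `"nearest"`
  mode is available for comparison.
* **ΔD50 sign**: `100 · (D50_eval − D50_ref) / D50_ref`, chosen so that
  *omitting* attenuating material makes the deviation positive.
* **Degenerate inputs** are errors, not warnings: empty ROIs, grids that
  clip the head or a placed component, beams that miss the density volume,
  fewer or more than four marker candidates, non-invertible LUT segments,
  equal-priority conflicting overrides.

## Problem sizes

The default cohort is ten phantoms of ≈4M voxels each at 1.5 mm. One static
field costs 0.5–2 s; the full sweep, the biased static-field study, and the
misplacement study each run in minutes on one core. The unit-test phantoms
use a narrower device stack and a smaller head (same code paths) to keep the
suite fast; the end-to-end property suite runs the full default geometry.

## Known limitations

The engine's lack of scatter and divergence means absolute doses are
internal units; only ratios are meaningful. The uniform mask shell cannot
reproduce the anterior nose-mold thickening, which in clinical data makes
the 0° beam the worst mask-only direction. Device edges are hard, which
exaggerates placement sensitivity relative to rounded real hardware.
Statistical testing across phantoms is intentionally absent: the cohort is
synthetic and seeded, so uncertainty statements reduce to the generator's
configuration.
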