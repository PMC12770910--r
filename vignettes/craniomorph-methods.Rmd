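---
title: "Methods: defacing-robust cranial morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defacing-robust cranial morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniomorph)
```

# The measurement problem

Extracranial tissues on brain MRI — cranial bone, subcutaneous fat and the
temporalis-type muscles — are quantifiable markers of sarcopenia,
cardiometabolic risk and cranial growth, but public MRI datasets are
anonymized by *defacing* algorithms that remove widely varying amounts of
anterior tissue. Two scans of the same head, defaced differently, yield
different "whole-head" tissue volumes. `craniomorph` operates downstream of
any whole-head segmentation tool: given a five-class label volume
(background, brain, skull, subcutaneous fat, muscle) and a binary brain
mask, it standardizes the measurement region, computes volumes and skull
thickness, and provides the agreement statistics used to validate such
pipelines. Everything is exercised on generated digital phantoms, so the
package carries no imaging data.

All volumes live on a canonical grid: the first array axis increases
posterior→anterior, the second right→left, the third inferior→superior.
NIfTI files in any orientation are reoriented on read (and the original
orientation is restored on write). Inputs are expected at roughly 1 mm
isotropic spacing, the resolution at which such scans are conventionally
resampled after rigid registration to an age-appropriate template;
volumetrics tolerate any spacing, but the thickness pipeline refuses
in-plane spacings outside [0.9, 1.1] mm rather than silently mis-scale
measurements whose constants (16 slices, 10 mm offset) assume ~1 mm voxels.

# The anterior cut

For a binary brain mask $S \in \{0,1\}^{H\times W\times D}$, each axial
slice $z$ (0-based, inferior to superior) contributes its most anterior
brain voxel

$$T(z) = \max\{\, x \in [0, H-1] : \exists\, y,\; S(x,y,z)=1 \,\},$$

with $T(z)=0$ where the slice holds no brain. The boundary is propagated as
a running maximum, $T^*(z) = \max(T(z),\, T^*(z-1))$ with $T^*(-1)=0$, so
the cutting surface can never move posteriorly in more superior slices.
Masks and images are then cropped by zeroing voxels with $x > T^*(z)$; the
boundary voxel itself is retained, following the strict inequality of the
defining rule.

Two consequences matter:

* **Brain voxels are never removed** — every brain voxel satisfies
  $x \le T(z) \le T^*(z)$.
* **Defacing invariance** — any defacing that only zeroes voxels strictly
  anterior to $T^*$ of the intact volume commutes with the crop, so the
  standardized ROI is voxel-identical across defacing variants. This is the
  property the whole construction exists for, and it is asserted
  voxel-for-voxel in the test suite for three simulated defacing styles.

Slices inferior to the brain (neck region) have $T(z)=0$ and inherit
$T^*=0$, so the crop leaves only the $x=0$ plane there. That is the
recurrence taken literally; callers who prefer to exclude the degenerate
neck region can pass `onlyBrainSlices = TRUE` to `standardizeROI()`, which
zeroes brain-free slices entirely without altering the core rule. The
boundary is exportable as a CSV audit table (`writeBoundary()`), 0-based to
match the recurrence.

# Volumetrics

`tissueVolumes()` counts voxels per non-background class and converts with
the voxel volume: $V_{\mathrm{cm}^3} = n \cdot s_x s_y s_z / 1000$, exactly.
No partial-volume modelling is attempted — the inputs are hard label masks,
and the quantities of interest are mask volumes. Reports carry raw counts
alongside cm³ so unit errors are auditable. `percentChange()` computes
signed per-class changes $100\,(V_\text{test}-V_\text{ref})/V_\text{ref}$;
a class absent from both reports is 0% change, absent only from the
reference is flagged undefined rather than infinite.

# Skull thickness

Thickness is estimated from a binary skull mask, slice by slice, over an
axial band chosen to avoid the frontal sinus and orbital cavities: starting
10 mm superior to an orbital-roof reference slice `z0` and spanning 16 mm
(with non-unit slice spacing, `round(16 / spacing)` slices — the band is a
physical extent, not a slice count). The reference slice is an explicit
input; a crude geometric fallback (`autoReferenceSlice()`: the most
inferior slice whose skull section is a closed, laterally spanning ring) is
provided for phantoms and quick looks, and is clearly not an anatomical
landmark detector.

Per slice:

1. The largest connected component of the 2-D section is taken; its
   boundary is the **outer contour**, and the boundary of its largest
   enclosed cavity is the **inner contour** (ordered vertex chains from
   contour tracing). A section without an enclosed cavity — a solid blob —
   is flagged degenerate and skipped.
2. **100 points** are placed uniformly by arc length along the outer
   contour, starting at the most anterior vertex (ties broken by the
   smaller lateral index).
3. At each point the local tangent is estimated by central difference over
   contour neighbours ±2 vertices, and thickness is measured along the
   **inward normal**: the term "tangent measurement" in this literature
   refers to the chord perpendicular to the local tangent — a tangent line
   itself has no finite intersection with the shell, so the normal chord is
   the only geometrically meaningful reading.
4. The normal ray is marched in 0.25-voxel steps (nearest-neighbour mask
   lookups, maximum length 50 mm), starting 2 voxels *outside* the contour
   point so that entry is detected at the pixelated outer surface rather
   than at a contour pixel centre — without this back-off, thickness is
   systematically underestimated by roughly half a voxel at staircase
   corners. Thickness is the entry→exit distance in mm. A sample is
   **missing** (not zero) when the ray leaves the slice, exceeds the
   maximum length, or exits into anything other than the central cavity —
   the latter is what makes rays through sinus-like pockets drop out
   instead of biasing the distribution.

Valid samples from all band slices (nominally 16 × 100) are pooled, values
outside the 2.5th–97.5th percentiles (linear interpolation between order
statistics) are discarded, and the median of the kept samples is reported.
The aggregation language in this field ("central 95% of values from over
100 tangents in each of 16 slices") supports pooling before trimming but
does not forbid per-slice trimming; pooling is the simpler reading and is
the default, with `perSliceTrim = TRUE` exposing the alternative — on
phantoms the two agree to well under a voxel. Fewer than 160 valid samples
(10% of nominal) is treated as an estimation failure, not a number.
Thickness uses the full skull mask rather than the cropped ROI: the
measurement band lies superior to the face, where the two coincide.

The CT reference segmentation (`ctSkullMask()`) thresholds a co-registered
CT at `HU > 471` by default (strict inequality), keeping the largest
6-connected component. Lower thresholds (~300 HU) include cancellous bone,
higher ones (~800 HU) only dense cortical bone; on the two-density phantom
the mask volume is non-increasing across the 300/400/500/800 HU sweep, and
a threshold above all bone attenuation returns an empty mask with a warning
rather than an error — mirroring how a subject without a valid contour at
an extreme threshold is excluded rather than crashed on.

On digital shells with walls of 3–10 mm at 1 mm voxels, the estimator
recovers the nominal wall within 0.25 mm (the ray-marching step) and orders
distinct walls strictly; an in-plane tilt of ±5° changes the median by at
most one voxel.

# Agreement statistics

* **Dice**: $2|A\cap B| / (|A|+|B|)$. Two empty masks are defined as Dice 1
  ("perfect agreement on absence") with an audit attribute, so per-class
  batch reports over classes absent from both segmentations do not
  propagate NaN.
* **HD95**: the 95th percentile of the pooled symmetric surface-to-surface
  distance distribution, in mm. Surfaces are mask voxels with a background
  face-neighbour (volume faces count as background); distances are exact
  Euclidean distance transforms with per-axis spacing, so anisotropic grids
  are handled correctly. Surface-based HD95 is the standard practice and is
  what makes the brute-force test oracle tractable; the choice is asserted
  by exact agreement with exhaustive pairwise computation on small masks.
* **Bland–Altman**: bias $= \overline{y-x}$ and 95% limits of agreement
  $\text{bias} \pm 1.96\,\mathrm{SD}(y-x)$.
* **Gwet's AC1**: $(p_a - p_e)/(1 - p_e)$ with chance agreement
  $p_e = \frac{1}{Q-1}\sum_q \pi_q (1-\pi_q)$, where $\pi_q$ averages the
  two raters' marginal proportions. AC1 is preferred over Cohen's kappa for
  acceptability ratings because it is robust to prevalence imbalance (most
  segmentations are acceptable). The confidence interval uses Gwet's
  subject-level linearized variance with a normal approximation, truncated
  above at 1 — the CI method is not dictated by the statistic itself, and
  this estimator is the standard one. Only pairwise-complete subjects
  contribute, and their count is reported.

# The phantom generator

Phantoms are geometric, not anatomically realistic: the validation surface
is *analytic recoverability*, not visual resemblance. A phantom comprises a
brain ellipsoid (default semi-axes 55 × 50 × 50 mm — deliberately slightly
smaller than an adult brain so that skull, fat, face and muscle fit a 160³
grid at 1 mm); a skull shell of constant nominal wall (each outer semi-axis
= brain + wall, default 5 mm); a 4 mm subcutaneous fat shell; two lateral
22 × 8 × 25 mm muscle ellipsoids placed one voxel clear of the fat surface
(temporalis-like in position and, at ~37 cm³ combined, in scale) so their
analytic volumes are exact; and an anterior half-ellipsoid "face"
protrusion (18 mm) that gives defacing and the anterior cut something to
remove. The head centre sits posterior of the grid centre so the face fits.
CT attenuation defaults: air −1000, brain 40, muscle 50, fat −100, cortical
bone 1000, optional cancellous sub-shell 450 HU (the `"two-density"`
preset, for the threshold sweep). T1-like intensities put fat bright and
bone dark on a [0, 1] scale. Noise is off by default so exact tests stay
exact; when enabled it is Gaussian, per class, and fully determined by the
seed.

What the phantom does *not* emulate — and hence what passing tests do not
establish about real data: MRI physics (bias fields, sequence contrast,
fat saturation), segmentation errors (phantom labels are perfect), true
cranial geometry (sutures, diploë, sinus complexity beyond simple enclosed
pockets), and partial-volume boundaries. The phantom validates the
*geometry and statistics* of the pipeline, not any segmentation model.

Perturbation harnesses mirror the robustness ablations used to validate
such pipelines: rigid tilt about the left–right axis (±5°,
nearest-neighbour for labels, bilinear for intensities, same grid);
three defacing styles (a flat sagittal plane at the global boundary
maximum, a wedge following the per-slice boundary on brain-bearing slices,
and an aggressive variant that follows the boundary on every slice) — all
constructed to cut strictly anterior to the intact propagated boundary
plus a non-negative margin, which is precisely the class of defacings the
ROI is invariant to; and five intensity augmentations (gamma 0.7/1.5,
brightness ±0.2 unclipped so opposite shifts invert exactly, rescaling to
[0, 1.2]) applied to the min–max-normalized volume.

On the default phantom, a ±5° tilt changes standardized-ROI class volumes
by ~0.3% on average (well under the 3% stability bound asserted in the
tests) and the thickness median by ≤ 1 voxel.

# Numerical choices and degenerate inputs

* Boundary indices are 0-based everywhere (object slots, CSV audit) to
  match the recurrence $T^*(-1)=0$ and the empty-slice convention.
* Ray marching: 0.25-voxel steps, 2-voxel entry back-off, 50 mm cap,
  nearest-neighbour lookups. Percentiles and the HD95 quantile use type-7
  linear interpolation.
* Ties for the "most anterior" contour start vertex break to the smallest
  lateral index; the inward normal orientation is chosen toward the inner
  cavity centroid.
* Empty brain mask → warning plus an all-zero boundary (still a valid
  object). Empty mask in Dice → defined result with a flag; in HD95 → an
  error, since no distance distribution exists. CT threshold above all
  attenuation → warning plus empty mask. Fewer than 160 valid thickness
  samples → error.
* The 3-D connected-component labelling and the exact separable Euclidean
  distance transform are small compiled kernels (no 3-D morphology with
  spacing support exists in the package's R dependencies); 2-D contour
  tracing, hole filling and labelling come from `EBImage`.

# Problem sizes and limitations

The test suite runs the full matrix — phantoms × {tilt, defacing,
intensity} × {crop, volumes, thickness, metrics} — at the default 160³
grid for acceptance-level properties and a 96³ phantom for unit tests, in
about a minute total; the reproduction script (`scripts/acceptance.R`)
regenerates its quantities in well under a minute. Known limitations:
thickness is resolved no finer than the ray step (0.25 voxel) and is not a
sub-voxel partial-volume estimate; cortical vs cancellous decomposition is
out of scope (the CT sweep treats them only via thresholds); the
orbital-roof reference slice must be supplied by the user on real data;
and DICOM ingestion, registration, brain extraction and intensity
normalization are deliberately outside the package — they belong to the
upstream segmentation pipeline.
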