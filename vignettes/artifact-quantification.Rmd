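---
title: "Threshold-based metal artifact quantification and its synthetic phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based metal artifact quantification and its synthetic phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maraq)
```

## The measurement problem

Metal implants distort CT numbers in their surroundings through beam
hardening and photon starvation, producing bright/dark streaks. To compare
acquisition protocols objectively one needs a number: *what fraction of a
clinically relevant volume is corrupted?* The method implemented here
answers that with a purely value-based classification:

1. **Reference statistics.** In an artifact-free section of the anatomy
   (here the distal femur, far from the implant), the mean and sample SD
   of CT numbers are measured per material — cortical bone, bone marrow,
   water.
2. **Thresholds.** Normal tissue is the closed interval
   `mean ± k·SD` (default `k = 3`). Under a normal distribution of CT
   numbers this encompasses 99.7% of artifact-free tissue. Thresholds are
   derived per tube potential from the conventional (energy-integrating,
   EID) acquisition, because CT numbers depend on the tube potential.
3. **Classification.** Every voxel outside the interval is an artifact;
   values exactly on a bound count as normal.
4. **VOI intersection.** The artifact segmentation of a series is the
   intersection of the out-of-range voxels with a volume of interest (the
   implant-bearing femoral shaft). The VOI is drawn once and copied to all
   series, which is valid because all series are acquired in the same
   position — the package enforces identical grids and never resamples.
5. **Correction.** Even artifact-free tissue leaves `2·Φ(−3) ≈ 0.27%`
   ("approximately 0.3%") of its voxels outside a ±3 SD interval, and the
   actual rate differs per acquisition (noise, reconstruction,
   CT-number shifts). The correction factor is therefore *measured* per
   series and material by applying the thresholds to that series' own
   artifact-free reference region, and subtracted from the raw
   percentage (floored at zero — a negative artifact volume is
   meaningless).

Two companion metrics complete the report: **noise**, the SD of CT
numbers in a water-bath-only acquisition (so no peripheral artifacts can
contaminate it), and **CNR** between each tissue and the water bath with
the phantom present.

### The CNR denominator

The published description of CNR — tissue/water contrast "relative to the
SD of water" — does not reproduce the published CNR table from the
published region statistics (for the Macro 140/75 cortical entry it gives
10.48 where 6.10 is printed). The quadratic mean of the two region SDs,

$$\mathrm{CNR} = \frac{|\mu_t - \mu_w|}{\sqrt{(\sigma_t^2 + \sigma_w^2)/2}},$$

reproduces **all 24 table cells to two decimals** (verified in the test
suite), so it is the package default; the literal water-SD form remains
available via `cnr(..., method = "water_sd")`.

## The synthetic phantom

No raw scans from the underlying study are publicly deposited, so the
package generates its own: `phantom_spec()` describes a 22 × 13 cm water
bath holding an elliptical foam femur (cortical shell, marrow core) with a
tapered metal stem — 5 × 4 cm diameters proximally, 3.2 × 3.6 cm at the
distal tip. Along z: a 7.2 cm artifact-free reference slab, a 10 cm gap,
then the implant zone overlapped by a 9 cm VOI beginning at the stem tip.
The default grid is 0.5 × 0.5 × 2 mm (in-plane detail with the protocol's
2 mm slice thickness); the examples and validation runs in this package
use 1 or 2 mm in-plane voxels, which keeps every stage comfortably fast
while leaving ≈10⁴–10⁵ voxels per analysis region.

Material HU means and per-protocol noise magnitudes come from the bundled
published reference table (`reference_series_stats()`): twelve protocols —
EID at 100/120/140 kVp, photon-counting Macro and Chess high-energy
threshold images at 55–75 keV. Metal is fixed at 3000 HU, a titanium-like
clipped value; its only requirement is to exceed every threshold.

### Noise model

Noise is additive, zero-mean Gaussian in HU with one global SD per series
(`add_noise()`), defaulting to the protocol's published water-bath-only
SD. This matches how the method itself measures noise — an SD over a
water region — and makes the ±3 SD machinery exactly calibrated: the
misclassification rate on artifact-free regions is `2·Φ(−k·SD_ref/σ)`.
A Chess-mode protocol without a configured SD inherits √2 × the same-kVp
Macro SD: each Chess threshold setting sees only half of the detector
subpixels. `simulate_detector_noise()` demonstrates the averaging law
directly (SD of a mean of *n* unit-variance subpixel samples is `1/√n`,
so halving *n* multiplies noise by ≈1.414).

What the global-σ model deliberately does **not** emulate is tissue
texture: real cortical bone has SD ≈ 81–142 HU in the reference table —
heterogeneity of the material itself, not detector noise. Consequently
CNRs computed *on synthetic volumes* are higher than the published ones
(the published values are reproduced from the published statistics, not
from simulation), and thresholds measured on synthetic references are
narrower than clinical ones. Tests that pass on the phantom therefore
validate the *pipeline arithmetic and its statistical calibration*, not
the biological variability of real tissue.

### Streak artifacts with ground truth

`inject_artifacts()` adds an analytic stand-in for beam-hardening streaks:
alternating hyper-/hypo-dense angular rays emanating from the stem axis,

$$p(\mathbf{x}) = A\,\operatorname{sign}(c)\,|c|^{m}\,
\frac{1}{1 + d/d_0}\,\frac{1}{1 + |z - z_\mathrm{tip}|/d_z},
\qquad c = \cos(n\theta + \varphi),$$

with $d$ the in-plane distance from the stem axis and $z_\mathrm{tip}$
the distal stem tip. The axial factor, anchored at the tip, gives the
characteristic negative trend of artifact load with distance from the
prosthesis; because its level sets are nested and the stem cross-section
shrinks toward the tip, the slice-wise truth fraction is *exactly*
non-increasing with distance — a property the test suite asserts without
tolerance. Voxels with $|p| >$ `truth_cutoff_hu` are recorded as ground
truth.

Design choices worth spelling out:

* **Truth cutoff = classification half-width.** The default cutoff is
  `3 ×` the noise SD of the *threshold-source* (EID) series — exactly the
  half-width of the downstream mean ± 3 SD rule. Any other choice makes
  "measured artifact percentage" and "injected truth" different
  quantities by definition, and recovery ill-posed.
* **Sharpness-calibrated targeting.** A requested ground-truth fraction
  (e.g. 10% of the marrow VOI) is met by fixing the amplitude at 10 × the
  cutoff and solving the ray exponent $m$ in closed form
  (`calibrate_streak_sharpness()`: a voxel is truth iff
  $m < (\log(c_0/A) - \log e)/\log|c|$, so $m$ is a quantile of that
  per-voxel bound). Calibrating the *amplitude* down instead would park
  it just above the cutoff and put a large voxel mass inside the
  noise-smeared transition band — in early experiments this biased
  recovered percentages by up to 8 points; with the sharpness approach
  the boundary band is thin and recovery errors stay below ≈0.4 points.
* **Seeding.** One master seed is fanned out per series and purpose
  through a stable string hash (`"streaks"`, `"<id>/p"`, `"<id>/w"`), so
  studies are bitwise reproducible, streak geometry is shared across
  co-registered series, and adding a series never changes the others.

## Numerical conventions

* Sample SD (n − 1) throughout; at region sizes of 10⁴–10⁶ voxels the
  population/sample distinction is negligible, and it is unbiased for the
  small fixtures in the tests.
* Closed "normal" interval: ties at a bound are normal tissue (the rule
  classifies what lies *beyond* the thresholds).
* Margins are metric: masks are eroded by their margin in mm with an
  exact anisotropic Euclidean distance transform (voxels whose distance
  to the mask complement strictly exceeds the margin survive). Defaults
  follow the protocol: 2 mm for bone regions, 30 mm for water. No
  hole-filling or connected-component cleanup is applied anywhere —
  classification is purely value-based.
* Reported precision follows the conventions of the field's tables:
  percentages to one decimal, CNR to two, HU to two.
* Volumes are written as signed 16-bit NIfTI (lossless for HU), masks as
  unsigned 8-bit, spacing in the header; grids must match exactly across
  series (no registration or resampling is in scope).

## What the validation shows — and its limits

The acceptance-style tests recover injected marrow truth fractions of 5,
10, 20 and 40% within 1.5 percentage points (EID self-thresholds recover
within ≈0.4), monotonically in the truth; they verify the √2 Chess/Macro
noise ratio, the ≈0.3% misclassification rate, the 99.7% coverage
identity, equivalence of the vectorised segmentation with a naive
per-voxel oracle, and the negative distance trend of measured artifact
percentages.

Two systematic effects of the *method itself* are visible in simulation
and worth knowing about when reading corrected percentages:

* The correction factor subtracts the false-positive rate as if the whole
  VOI were artifact-free, over-subtracting by roughly
  `truth × FP-rate` — negligible for EID (≈0.03 points at 10% truth),
  ≈2 points for Chess-mode noise under EID-derived thresholds. At the
  simulated 10% marrow condition this keeps the Chess–Macro difference
  near the recovery tolerance rather than well inside it.
* Systematic CT-number shifts between detector types (e.g. cortical bone
  ≈84 HU lower in Macro mode than in EID at 140 kVp) inflate both the raw
  percentage and the correction factor; the subtraction only partially
  cancels, so corrected cortical percentages for photon-counting series
  are biased low. The published discussion flags the same CT-number
  shifts; the simulation simply makes the consequence measurable.

Neither effect is "fixed" here, because the package's job is to implement
the method as published; both are reported transparently through the
`truth_percent` column of simulated studies.

The published phantom artifact percentages themselves (e.g. bone-marrow
ranges per mode) are **not** reproduction targets: they depend on the
actual scanner physics and undeposited raw data. The synthetic phantom
validates the measurement machinery, not the physics.
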