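# maraq — metal artifact quantification for CT volumes

Metal implants such as hip prostheses produce beam-hardening and streak
artifacts in CT images that degrade diagnostic quality around the implant.
`maraq` implements the semi-automated, threshold-based method for
*quantifying* those artifacts that is used to compare acquisition protocols
(conventional energy-integrating detector CT versus photon-counting
detector CT with high-energy thresholding in Macro or Chess mode): given
co-registered series of a phantom or patient, it measures what percentage
of a volume of interest (VOI) is corrupted by artifacts, along with image
noise and contrast-to-noise ratios (CNR). It is aimed at medical-physics
and radiology researchers evaluating artifact-reduction strategies.

## Method

For each material *m* (cortical bone, bone marrow, water) and tube
potential, HU statistics are measured in an artifact-free reference
segmentation of a conventional (EID) acquisition, and "normal" tissue is
defined by the closed interval

```
[ mean_m − k·SD_m ,  mean_m + k·SD_m ]        (default k = 3)
```

which under a normal distribution of CT numbers encompasses 99.7% of
artifact-free tissue. Voxels of a series falling outside the interval are
classified as artifacts; the artifact segmentation of a VOI is the
intersection of the VOI with those out-of-range voxels, and the raw
artifact percentage is `100·|artifact ∩ VOI| / |VOI|`. Because the ±3 SD
rule misclassifies ≈ 0.3% of normal voxels (analytically `2·Φ(−3)`), a
correction factor — the out-of-range percentage measured on the series'
own artifact-free reference region — is subtracted and the result floored
at zero. Noise is the SD of CT numbers in a water-bath-only companion
acquisition; CNR is `|mean_tissue − mean_water| /
sqrt((SD_tissue² + SD_water²)/2)`.

Because the phantom and cadaver scans behind the method are not publicly
deposited, the package ships a synthetic phantom generator that emulates
the study conditions: a water bath (22 × 13 cm) holding a foam femur model
(cortical shell + marrow core) with a tapered metal stem (5 × 4 cm proximal
to 3.2 × 3.6 cm distal), material HU means taken from the published
per-protocol reference table, streak artifacts decaying with distance from
the prosthesis, Gaussian image noise per protocol, and Chess-mode noise at
√2 × Macro-mode noise. The generator records a ground-truth artifact mask,
so the pipeline's accuracy can be validated end to end.

## Worked example

```r
library(maraq)
cfg <- load_config(system.file("extdata", "example_study.yaml",
                               package = "maraq"))
fit <- run_study(cfg)
fit
```

```
<artifact_study> 3 series x 3 materials (seed 42)

           series      material  raw correction corrected truth
       EID-CT 140 cortical_bone  9.6        0.2       9.4   9.2
       EID-CT 140   bone_marrow 10.6        0.3      10.3  10.4
       EID-CT 140         water  4.9        0.3       4.6   3.9
 Macro-HTI 140/75 cortical_bone 43.3       39.5       3.8   9.2
 Macro-HTI 140/75   bone_marrow 19.0       10.4       8.6  10.4
 Macro-HTI 140/75         water 11.6        7.5       4.1   3.9
 Chess-HTI 140/75 cortical_bone 39.8       34.9       4.9   9.2
 Chess-HTI 140/75   bone_marrow 27.4       20.6       6.8  10.4
 Chess-HTI 140/75         water 23.4       20.3       3.1   3.9

Noise (HU SD, water bath only):
           series noise_hu
       EID-CT 140    32.97
 Macro-HTI 140/75    55.25
 Chess-HTI 140/75    77.27
```

Reading the output: a ground-truth artifact load of 10% was injected into
the bone-marrow VOI. The EID series (whose reference region also supplies
the thresholds for the two photon-counting series at the same tube
potential) recovers it almost exactly (10.3 vs 10.4). The photon-counting
series are noisier (55 and 77 HU vs 33 HU — Chess ≈ √2 × Macro), so their
raw percentages are inflated by false positives; the per-series correction
factor removes most of that inflation (e.g. Chess marrow 27.4% raw −
20.6% correction = 6.8%). The large cortical-bone corrections reflect the
systematic CT-number shift between detector types, which the correction
factor can only partially absorb — a real limitation of the method that
the simulation reproduces. Per-slice distance profiles (`fit$profiles`)
show the artifact percentage falling with distance from the prosthesis
tip.

`write_study_results(fit, "out/")` saves `results.csv`,
`thresholds.csv`, `noise.csv`, `cnr.csv`, `profiles.csv` and
`study.json`; re-running the same config and seed reproduces them byte
for byte. A thin CLI over the same functions is provided in
`inst/scripts/maraq.R`.

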