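---
title: "Colourimetric temperature estimation for burned bone: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colourimetric temperature estimation for burned bone: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonetemp)
```

## The problem

When skeletal remains are recovered from a fire, the temperature the bone was
exposed to carries forensic and archaeological information: it constrains the
reconstruction of the fire, and it predicts whether DNA or isotope profiling
is still feasible. Heat changes bone colour in a characteristic sequence —
ivory white, darkening through brown to carbonized black as collagen
pyrolyzes, then grey ("inversion"), and finally calcined grey-white once the
residual carbon has burned away (roughly above 700 °C). `bonetemp` turns that
sequence into an objective, non-destructive measurement: colour coordinates
are read from a calibrated scan or photograph of the fragment and mapped to
an exposure-temperature range.

## The decision model

The core of the package is a fixed rule set in the CIE 1976 L\*a\*b\* colour
space. Of the three coordinates, lightness L\* and the blue–yellow coordinate
B\* discriminate the heat-induced stages best; the green–red coordinate A\* is
so strongly correlated with B\* that it adds essentially nothing and is
ignored by the classifier (it is still accepted and carried through
measurement tables). Seven clusters partition the (L\*, B\*) plane:

| cluster | region | range (°C) | HI stage |
|---|---|---|---|
| 1 | B\* > 11, L\* ≥ 40 | 0–350 | unheated – carbonization |
| 2 | B\* > 11, L\* < 40 | 250–350 | carbonization |
| 3 | B\* ≤ 11, L\* < 32.5 | 300–600 | completely charred |
| 4 | B\* ≤ 11, 32.5 ≤ L\* < 75, B\* ≥ 6.5 | 450–600 | inversion |
| 5 | B\* ≤ 11, 32.5 ≤ L\* < 75, B\* < 6.5 | 450–700 | inversion – calcination |
| 6 | B\* ≤ 11, L\* ≥ 75, L\* ≤ −25·B\* + 200 | 700 – ≥900 | completely calcined |
| 7 | B\* ≤ 11, L\* ≥ 75, L\* > −25·B\* + 200 | 800 – ≥900 | completely calcined |

The thresholds (40, 32.5, 75 on L\*; 11, 6.5 on B\*; the line
L\* = −25·B\* + 200) are fixed published constants; `decision_thresholds()`
exposes them only so that sensitivity analyses can perturb them. They are
coherent only on the standard CIE scales — L\* in 0–100 and signed a\*/b\* —
which is why the package never adopts the 0–255 Lab encoding some image
software uses.

Two aspects of the rule set as printed are under-determined and are resolved
here as explicit design choices:

* **The cluster 4/5 overlap.** As printed, cluster 4 admits B\* < 11 and
  cluster 5 B\* < 6.5, so the B\* < 6.5 strip would satisfy both. `bonetemp`
  implements cluster 4 as 6.5 ≤ B\* ≤ 11 and cluster 5 as B\* < 6.5 (within
  32.5 ≤ L\* < 75), which matches the drawn boundary between the two regions
  and keeps the temperature ordering coherent.
* **Ties at exact thresholds.** Points landing exactly on a threshold are
  assigned by a half-open scheme (B\* = 11 joins the B\* ≤ 11 side; L\* = 40
  joins cluster 1; L\* = 32.5 and 75 join the higher-L\* region; a point
  exactly on the −25·B\* + 200 line joins cluster 6). Where a choice existed
  it goes to the lower-temperature cluster: under-reporting the temperature
  is the forensically conservative error.

With these resolutions the seven regions form a total, mutually exclusive
partition of L\* ∈ [0,100] × B\* ∈ [−128,127]; the test suite verifies this by
brute-force enumeration over a 0.1-step grid (~2.6 million points) and checks
that the classifier's discontinuities fall exactly on the published
boundaries.

Each cluster reports a temperature range, not a point estimate: the ranges
are the empirical minima/maxima observed among learning samples in each
cluster, and their widths differ (clusters 2, 4 and 7 are narrow; 1, 3, 5
and 6 wide). The upper bound of clusters 6 and 7 is open — 900 °C was merely
the highest exposure used — and is displayed as "≥900".

## Colour measurement

**Conversion.** `srgb_to_lab()`/`lab_to_srgb()` implement the standard sRGB
companding and the CIE 1976 equations. D65 is the default reference white
(the sRGB native white and the common flatbed/ImageJ convention; the
originating workflow does not state one), with D50 available. The reference
white is taken as the row sums of the RGB→XYZ matrix rather than the
separately rounded textbook constants, so that greyscale inputs are exactly
neutral (a\* = b\* = 0) instead of neutral only to ~10⁻⁵; the difference is
far below measurement noise but keeps the neutral-axis invariant exact.
Out-of-gamut results of the inverse transform are clipped to the channel
range and flagged, never silently altered.

**Calibration.** Scanners and cameras are calibrated against a 24-patch
reference chart (`colorchecker_reference()` ships nominal sRGB values).
`fit_colour_correction()` fits a least-squares map from measured to reference
colours *in linearised RGB*, where device mixing is closest to linear. The
default is affine (3×3 matrix plus offset), which absorbs a scanner
black-level offset; a pure 3×3 linear model is available. Residuals are
summarised as per-patch ΔE\*ab (plain Euclidean distance in Lab — adequate
for chart quality control; no perceptual refinement is attempted). Four
non-degenerate patches are the minimum for the affine fit; a rank-deficient
patch set (e.g. greys only) is an error, not a warning.

**ROI measurement.** Samples are scanned on a white background.
`segment_sample()` takes pixels with L\* below 90 as candidate foreground
(Otsu thresholding is a fallback for non-standard backgrounds), keeps the
largest connected component and fills holes. `erode_rim()` then excludes an
outer rim — by default 1.5 mm, the midpoint of the 1–2 mm practice — by
eroding the mask with a Euclidean disk of radius `round(rim_mm · dpi / 25.4)`
pixels. The rim exclusion is the sole defence against edge overexposure,
chromatic aberration and soot creeping over the edge; no deconvolution is
attempted. A post-erosion ROI below 100 pixels is rejected (the mean of a
smaller region is too unstable); the minimum is configurable.
`measure_mean_colour()` reports the arithmetic mean RGB and the **mean of
per-pixel Lab values** — the convention of the common image-analysis
plugins — rather than the Lab of the mean RGB; on textured samples the two
differ because the conversion is nonlinear. Manual masks can be imported
(`import_roi_mask()`) where automated segmentation is not trusted.

## Heat maps

A fragment burned under a thermal gradient spans several clusters.
`classify_pixels()` applies the decision model per pixel after averaging each
pixel's Lab over a small window restricted to the mask (default 5 px —
enough to suppress sensor noise without erasing genuine zone boundaries;
per-pixel classification is inherently noisier than the ROI-mean pathway).
`summarise_map()` reports the per-cluster pixel fractions and a combined
temperature envelope: the minimum over present clusters' minima to the
maximum over their maxima, open-ended if cluster 6 or 7 is present. The map
renders to an indexed PNG with a fixed 8-colour legend.

## Supporting statistics

`pearson_r()` and `correlation_matrix()` reproduce the parameter-screening
step (RGB channels correlate near-perfectly with L\*, hence the move to
L\*a\*b\*; A\* and B\* correlate strongly with each other, hence the L\*/B\*
plane). `standardized_mlr()` fits ordinary least squares and reports, per
predictor, the standardized coefficient β = b·σₓ/σᵧ, the semi-partial (part)
correlation (computed as t·√(1−R²)/√(n−k−1), identical to correlating the
response with the predictor residualised on the others), and a two-sided
p-value from the t distribution. No multiple-testing correction is applied
(raw p-values at α = 0.05, matching the original analysis). The medium is
coded air = 0 / adipose = 1; age is grouped <60 / 60–80 / >80 and expanded
into two dummies. With one predictor, β = part = Pearson r — an identity the
tests check to 10⁻¹⁰. MANOVA-style omnibus testing is deliberately out of
scope; the dataset carries the factors so standard R tools can be applied
directly.

`cluster_temperature_ranges()` recomputes the empirical per-cluster
temperature ranges from any dataset with known exposure temperatures — the
procedure that produced the published ranges.

## Validation scoring

`score_prediction()` scores an estimate 1 when the true temperature lies
inside the assigned cluster's range (upper bound +∞ for clusters 6/7), else
0. "Correct" is thus *range containment* — the source never defines it
operationally, so this interpretation is stated prominently; note it implies
a cluster-1 assignment (range starting at 0 °C) is correct for a genuinely
unheated sample. `accuracy_report()` gives per-partition percentages plus an
overall figure under **both** conventions — pooling all samples (weighted) or
averaging partition accuracies (unweighted) — because published totals of
this kind are computed inconsistently between the two; the weighted pooling
is the default, and both numbers are always present in the object.

## The synthetic-data generator

Real heated-bone learning sets cannot be shipped, so `trajectory_model()` and
`generate_dataset()` emulate their structure: a piecewise-linear trajectory
of mean L\*/A\*/B\* through temperature anchors at 20, 300, 500, 650, 800 and
900 °C, Gaussian per-channel noise of σ = 2 Lab units (the small
within-subgroup spread typical of such data), and small additive effects of
exposure duration (−0.03 L\*/min, −0.02 B\*/min around a 20-minute reference)
and of heating in adipose tissue (+1 L\*, +0.4 B\*) — an order of magnitude
below the temperature effect, so that temperature dominates, reproducing the
sign and dominance structure of the published regressions. The default
design crosses those temperatures with 10–30 minute durations at n = 10 per
subgroup; adipose combinations above 450 °C are dropped, as autoignition
makes such exposures uncontrollable in practice.

Anchor means follow the described colour path (ivory (65, 18) → carbonized
brownish-black (25, 17) → charred (26, 6) → grey (58, 1) → calcined white
(85, −0.5) and (92, −1), quoting (L\*, B\*)). Two placement rules were applied
once, at design time: each anchor lies inside the region of a cluster whose
temperature range contains the anchor temperature, and at a **Euclidean**
distance of at least ~2.5σ from every decision boundary. The second rule
needs care near the calcined boundary L\* = −25·B\* + 200: its steep slope
means the distance is |200 − L\* − 25·B\*|/√626, so B\* noise dominates and
plausible-looking anchors with b\* ≈ 1 would sit under 2σ away and leak into
cluster 7. The calcined anchors therefore use slightly negative b\* (a
bluish-white, realistic for fully calcined bone). No anchor targets cluster
4: its B\* band (6.5–11) is only 4.5 units wide, so no mean can be ≥2.5σ from
both edges at σ = 2 — a limitation of the generator, not of the classifier.

`render_sample_image()` produces elliptical "transverse slices" on a white
background with optional per-pixel noise and an optional contaminated rim of
stated physical width (the soot fixture for the rim-exclusion tests);
`render_chart_image()`/`chart_patch_means()` provide the calibration
fixtures. Fixing the seed fixes every generated object exactly.

**What the generator does not emulate.** Real data have temperature-dependent
(not constant) subgroup variances, occasional bluish/greenish/pinkish metal
tints, incomplete-combustion artefacts, surface texture, and inter-individual
biology. Passing tests on synthetic data therefore demonstrate the
correctness of the algorithms and the internal coherence of the decision
rules under the stated noise model — not field accuracy, which only the
original validation against physically burned bone addresses.

## Numerical choices and problem sizes

* Internal image processing is floating point on [0,1]; 8- and 16-bit
  TIFF/PNG are accepted.
* The partition check enumerates the full 0.1-step grid (~2.6 M points); all
  other tests run on small fixtures (disks of radius ≤ 50 px, datasets of
  90–240 records, 50 draws per anchor), sizes at which every expected value
  is either exact or has a comfortable probabilistic margin under the fixed
  seeds.
* Erosion uses the exact Euclidean distance transform rather than an
  approximate structuring element, so eroded areas track the analytic
  geometry to within discretisation error (<3% for the fixture sizes used).
* Degenerate inputs fail loudly: empty segmentations, too-small ROIs,
  rank-deficient calibration charts, zero-variance correlations and collinear
  regression designs are all errors with informative messages.

## Known limitations

* The decision thresholds are taken as fixed constants; the package does not
  re-derive them from data (the original cluster identification was manual),
  and offers no probabilistic temperature estimate or machine-learning
  classifier.
* Results are only as good as the calibration: uncalibrated or
  white-balance-shifted images will misclassify, particularly near the B\* =
  11 and 6.5 thresholds.
* The model applies to adult human bone measured on clean surfaces; soot
  deposits mimic charring (hence the rim exclusion, which cannot help if the
  whole surface is contaminated), and stained or diagenetically altered bone
  is outside the model's domain.
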