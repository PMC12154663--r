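---
title: "Methods: robust color phenotyping and breakpoint detection in floracline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust color phenotyping and breakpoint detection in floracline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floracline)
```

## The problem

Widespread flowering plants can show continuous geographic variation in
flower color that is hard to assess from herbarium work alone. Community
science platforms now hold tens of thousands of georeferenced photographs of
single species, which makes a statistical treatment possible — provided the
pipeline is robust to the noise inherent in uncontrolled photography:
variable lighting, backgrounds, and imperfect segmentation.

`floracline` implements such a pipeline for a wild bergamot-like scenario:
a North American wildflower with lavender-to-violet corollas whose western,
montane populations are hypothesized to be darker and more chromatic than
the eastern ones, with essentially the same hue. The package extracts one
robust color per image, one color per observation, and then asks where along
the longitudinal gradient the multivariate color distribution splits most
sharply.

## Color representation

All numerical work happens in CIELAB (D65 white point, 2° observer), a
three-dimensional, approximately perceptually uniform space: `L` (lightness,
0–100), `a` (green–red), `b` (blue–yellow). LCh — the same space in
cylindrical coordinates, with chroma $C = \sqrt{a^2 + b^2}$ and hue
$h = \mathrm{atan2}(b, a)$ — is derived afterwards for interpretation,
because lightness/chroma/hue map onto the field vocabulary ("darker",
"more saturated", "same hue").

Numerical conventions:

* The illuminant/observer choice (D65/2°) follows the default of the common
  color libraries; at the effect sizes studied the results are insensitive
  to it, but it is fixed and recorded.
* Hue of achromatic colors ($C < 10^{-8}$) is defined as 0°, since
  `atan2(0, 0)` is undefined and grays otherwise acquire an arbitrary hue
  from floating-point noise. This keeps outlier classification
  deterministic.
* Lab→sRGB clips out-of-gamut channels in linear light; the inverse path is
  only used to produce display hex codes, never for analysis.
* Averaging of colors (cell means, medians) is always done in Cartesian
  CIELAB; hue is circular and polar averaging is invalid.

## From pixels to one phenotype per observation

**Segmentation.** Flower pixels are identified by a transparent LCh
threshold classifier: a pixel is "flower" iff chroma ≥ 12, lightness in
[15, 97], and hue in [0°, 50°] ∪ [250°, 360°] — the purple/violet hue ranges
that bound wild-type corolla colors. This plays the role a trained semantic
segmentation model would play at production scale; it is deliberately
simple, fully configurable (`segmenter_config()`), and exactly reproducible,
which is what the downstream statistics need for verification. Masks persist
as a small JSON dialect: row-major run lengths alternating 0-runs and
1-runs, starting with a (possibly empty) 0-run. Readers accept only this
dialect and fail loudly, naming the offending field. Mask quality is scored
by mean intersection-over-union over the two classes, with an absent class
contributing IoU 1 so single-class toy images score sensibly.

**Robust color per image.** The masked pixels' CIELAB values are reduced to
their *geometric median* — the point minimizing the sum of Euclidean
distances, with a 50% breakdown point. This is the package's central
robustness device: stray background pixels that survive segmentation pull
the mean far more than the median. The Weiszfeld iteration starts at the
coordinate-wise mean, stops when successive iterates move less than
`tol = 1e-7` Lab units (cap 1000 iterations), and applies the Vardi–Zhang
correction when an iterate lands on a data point (within $10^{-12}$), where
the plain update would divide by zero. The tolerance and cap are exposed
arguments, so they are auditable; at 8-bit pixel quantization anything below
~0.05 Lab units is already beyond measurement precision.

**One image per observation.** Observations with several images contribute
exactly one, chosen uniformly under a caller-supplied seed. The seed is a
required argument — there is no silent default — because this is the one
sampling step in an otherwise deterministic pipeline. Images that produce
no flower pixels (e.g. white morphs under the chroma threshold, unreadable
files) are logged to a failures table and excluded, not raised: at
production scale a small failure count is expected and tolerated.

## Spatial aggregation and the regional contrast

Coordinates project through a sinusoidal equal-area projection
($x = R\lambda\cos\varphi$, $y = R\varphi$, $R = 6371$ km), chosen because
it gives equal-area cells with no external geodesy dependency. Phenotypes
are averaged (componentwise in Lab) within 200 km × 200 km cells for
mapping; the statistical tests use the raw per-observation values.

The fixed regional contrast splits at −100° longitude ("west" strictly less;
equality goes east, since the western region is defined strictly). The
two-sample **Hotelling T²**

$$T^2 = \frac{nm}{n+m}\, \bar d' S^{-1} \bar d, \qquad
F = \frac{n+m-p-1}{p\,(n+m-2)}\,T^2 \sim F_{p,\; n+m-p-1}$$

compares the 3-dimensional mean color vectors under the pooled covariance
$S$; the effect size is the multivariate partial
$\eta^2 = T^2/(T^2 + n + m - 2)$.

## Localizing the cline without a prior boundary

Two independent procedures ask where the data themselves put the divide:

1. **Sliding T² scan.** 1000 candidate split longitudes, evenly spaced
   (inclusive endpoints) between the observed minimum and maximum. At each,
   the data split west/east and T² is computed if both sides hold ≥ 100
   observations (positions failing that are reported as missing). The
   breakpoint estimate is the arg-max; ties break toward the westmost
   candidate so the estimate is deterministic. No multiple-testing
   correction is applied across positions — the scan is exploratory
   localization, and its output metadata says so.
2. **k-means profile.** k-means (Lloyd, k = 2, best of 10 seeded restarts)
   clusters the colors with no geographic input; labels are canonicalized so
   cluster 1 is the darker one (lower mean L). The mean label in a ±1°
   window around each of the same 1000 longitudes traces the transition; the
   profile's first drop below 0.5 is an independent estimate of the divide.

A third validation flags **hue outliers**: phenotypes with hue strictly
inside [50°, 250°], i.e. outside the purple ranges. In both the real-world
motivation and the synthetic generator these are white-flowered individuals,
whose near-achromatic colors have unstable hue.

## Lighting-bias validation

Could a west–east difference be an exposure artifact — sunnier photographs
looking lighter? The validation battery works on a rated subset of images,
binned by two raters into shade / partial sun / full sun (with a "NAN"
opt-out):

* **Cohen's κ** for inter-rater agreement, CI from the asymptotic
  Fleiss–Cohen–Everitt standard error with the 1.96 normal quantile (the
  method is stated because several CI recipes circulate).
* **Pearson χ²** (no continuity correction) testing that lighting
  composition does not differ between regions, on the *consensus* subset —
  items where both raters chose the same non-NAN category.
* **Two-way ANOVAs** per CIELAB component and a **joint MANOVA**
  (Pillai's trace with the standard F approximation) of color on
  region × lighting, with Type II sums of squares and treatment coding
  (reference levels: east, shade — so the `lightingfull` coefficient on L is
  the full-sun lightening in L units). The interaction term is the key
  readout: a non-significant interaction means the regional difference is
  consistent across lighting conditions. Type II was chosen because the
  rated subset is unbalanced by design; under balance it coincides with
  Type III (tested).

## The synthetic generator: what it emulates, and what it does not

`synth_config()` / `generate_observations()` define the study conditions for
every verification in the package:

* ~uniform longitudes over [−135.3°, −61.4°], latitudes [25°, 55°] (latitude
  is a nuisance dimension; the analysis is longitudinal).
* Two regional color regimes split at −100°: west LCh (55, 38, 315°), east
  (68, 26, 315°) — i.e. ΔL = −13, ΔC = +12, identical hue, expressed and
  perturbed in Lab with per-component SD (6, 4, 4). The SD is the one
  genuinely free parameter; it was fixed once at a level that reproduces the
  qualitative field pattern the analysis is designed to detect (cluster
  profile above 0.8 west of the transition and below 0.3 east of it, hue
  difference under 3°). Real photograph collections are noisier — their
  regional effect sizes (partial η²) are smaller than this generator's — so
  passing tests demonstrate correctness of the machinery, not the field
  effect size.
* 0.7% white morphs: L ~ N(92, 2), chroma ~ U(1, 6), hue ~ U(60°, 240°) —
  high lightness, near-zero chroma, unstable non-purple hue, exactly the
  signature the hue-outlier rule targets.
* 25% of observations carry 2 images (≈1.24 images/observation, matching
  the multi-image rate of large community datasets).
* Lighting: shade/partial/full with probabilities 0.3/0.4/0.3; full sun adds
  +10 to the *observed* L only. The true phenotype is untouched — lighting
  is modeled as an exposure artifact, not biology — so the planted
  `lightingfull` coefficient is exactly +10 with no region × lighting
  interaction.
* Raters report the true lighting with independent mislabeling probability
  0.15 and a 2% "NAN" rate. 0.15 was chosen once as a realistic
  disagreement level for a 3-category judgment call; it implies ~73%
  raw agreement and κ ≈ 0.6.
* Rendered images (default 32 × 32) place 1–3 uniform-color discs (≥5%
  coverage, per-pixel RGB jitter SD 2) on a green/olive textured background
  whose hue stays inside (50°, 250°) even at the noise extremes, so
  background pixels can never enter the purple segmentation windows. The
  mask is the disc set by construction. The renders are deliberately
  non-photorealistic: they verify the plumbing (segmentation → extraction →
  median → analysis), not computer-vision difficulty.

Everything is deterministic given the config seed: the same configuration
yields byte-identical cohorts on disk, and the pipeline writes no timestamps,
so full reruns are byte-identical too.

## Numerical and design choices worth knowing

* **Scan grid**: inclusive endpoints, exactly `n_points` values; with
  `min_group` unmet at the edges the statistic is missing there, never
  extrapolated. Degenerate inputs (all observations at one longitude, or
  fewer than `2 * min_group`) are errors, not empty results.
* **Prefix-moment scan**: the scan computes all split statistics from
  cumulative first and second moments along the sorted longitudes, so a
  1000-point scan over 5000 observations costs well under a second; the
  direct two-sample implementation (`hotelling_t2()`) is kept as the
  reference path and the two agree to floating-point accuracy.
* **Singular covariances** anywhere in the scan yield a missing value at
  that position; in the two-sample test they raise an error advising
  variable removal.
* **k-means canonicalization** by mean lightness makes cluster labels (and
  hence profiles) reproducible across seeds even though the clustering
  itself is label-symmetric.
* **IoU convention**: a class absent from both masks scores 1.
* **Hue windows** in the segmenter are closed; an upper bound of 360° also
  admits h = 0 (360 ≡ 0).
* **Problem sizes in the test suite** were chosen to make every stochastic
  check decisive at desk scale: 10,000-color round trips, 50-point-set
  optimizer comparisons, 2000-replicate null calibrations, 20 cohorts of
  5000 observations for breakpoint recovery, and a 150-observation
  image-rendering cohort for the end-to-end pipeline.

## Known limitations

* The threshold segmenter is a verification-grade stand-in: on real
  photographs a trained segmentation model is needed, and the package's
  mask I/O and IoU tooling are the interface to plug one in. Its accuracy
  here is only validated on synthetic fixtures.
* Each image is reduced to a single color; within-image color distributions
  (gradients, multi-tone corollas) are out of scope.
* The generator does not model spatially autocorrelated noise, camera
  response curves, or photorealistic scenes; conclusions about real-data
  effect sizes cannot be read off the synthetic results.
* Grid cells are axis-aligned in the projected plane; no geodesic
  corrections are applied.
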