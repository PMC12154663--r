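# floracline

Flower-color phenotyping and geographic divergence analysis from
community-science images.

## The problem

Many widespread wildflowers are suspected of continuous geographic variation
in flower color — for example a western, montane variety with darker, more
chromatic violet corollas than its pale-lavender eastern relatives. Testing
that at scale from community-science photographs requires a pipeline that is
robust to uncontrolled lighting and backgrounds, and a statistical battery
that can both *test* a hypothesized regional boundary and *localize* the
boundary with no prior. `floracline` provides both, plus the validation
tooling (segmentation scoring, outlier screening, inter-rater agreement,
lighting-bias models) and a synthetic-data generator with planted ground
truth so every stage can be verified end to end.

## The method in brief

- **Per-image color**: flower pixels (binary mask, persisted as an RLE JSON
  dialect) are converted to CIELAB and reduced to their **geometric
  median** — the minimizer of `sum_i ||y - x_i||`, computed by Weiszfeld
  iteration with the Vardi–Zhang correction — a 50%-breakdown robust
  alternative to the mean.
- **Per-observation color**: one image per observation, sampled under a
  required seed; LCh (`C = sqrt(a^2 + b^2)`, `h = atan2(b, a)`) and hex are
  derived for interpretation.
- **Regional contrast**: two-sample **Hotelling T²**,
  `T² = nm/(n+m) · d' S⁻¹ d`, with
  `F = T²(n+m−p−1)/(p(n+m−2)) ~ F(p, n+m−p−1)` and multivariate partial
  `η² = T²/(T² + n + m − 2)`, comparing colors west vs east of a −100°
  longitude split.
- **Breakpoint localization**: a sliding T² scan over 1000 evenly spaced
  candidate longitudes (≥100 observations required per side), plus an
  independent k-means (k = 2) **cluster profile** — the ±1°-windowed mean of
  darkness-canonicalized cluster labels.
- **Validation**: mean IoU of masks against ground truth; hue-window outlier
  screening (hue strictly in [50°, 250°] = non-purple); Cohen's κ with the
  Fleiss–Cohen–Everitt asymptotic CI; Pearson χ² for regional lighting
  composition; Type II two-way ANOVAs and a Pillai-trace MANOVA of color on
  region × lighting.

See `vignettes/floracline-methods.Rmd` for the full account of the model,
parameters, and numerical conventions.

## Worked example

Generate a 5000-observation synthetic cohort with the default planted
structure (west/east divide at −100°, ΔL = −13, ΔC = +12, same hue 315°,
0.7% white morphs) and run the analysis battery:

```r
library(floracline)

cfg <- synth_config(seed = 1, n_observations = 5000)
g   <- generate_observations(cfg)
lab <- as.matrix(g$truth[, c("L", "a", "b")])

region <- assign_region(g$truth$longitude)          # split at -100
hotelling_t2(lab[region == "west", ], lab[region == "east", ])
#> Hotelling's T2 = 8348.52, F(3, 4996) = 2781.73, p = 0, partial eta2 = 62.6% (n = 2446 vs 2554)

sliding_breakpoint_scan(lab, g$truth$longitude)
#> Breakpoint scan over 1000 longitudes [-135.29, -61.41], n = 5000 (min_group = 100)
#>   peak T2 = 8290.09 at longitude -100.009

cluster_profile(kmeans_two(lab, seed = 2), g$truth$longitude)
#> Cluster profile over 1000 windows (halfwidth 1.0 deg); crosses 0.5 at -100.009

out <- classify_hue_outliers(g$truth)
sprintf("hue outliers: %d of %d (%.2f%%)", out$n_flagged, 5000, 100 * out$fraction)
#> "hue outliers: 41 of 5000 (0.82%)"
```

The regional test finds a very large multivariate color difference; both the
T² scan and the geography-blind k-means profile localize the planted divide
at −100.01°, and the hue-outlier rule recovers essentially the planted
white-morph rate (0.7%, here 0.82% by sampling noise).

The image-level pipeline (`generate_cohort()` → `run_pipeline()`) runs the
same analysis from rendered PNGs: threshold segmentation, mask persistence,
geometric-median phenotyping with a failures log, grid aggregation, and the
full analysis battery, writing CSV/JSON outputs and a run manifest whose
counts reconcile (images in = phenotyped + failed). Reruns with the same
configuration are byte-identical.

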