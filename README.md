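# orgredox

Automated image analysis and statistics for **wide-field one-photon redox
imaging of patient-derived cancer organoids (PCOs)**.

Redox imaging reads cellular metabolism non-destructively from the
autofluorescence of NAD(P)H and FAD. On a standard wide-field
epifluorescence microscope, each well yields a two-channel image time
series over a 48-hour treatment course, from which the per-pixel
**optical redox ratio**

```
ORR(i,j) = NAD(P)H(i,j) / (FAD(i,j) + NAD(P)H(i,j))
```

maps the local oxidation–reduction state. Drug response typically lowers
both the ORR and the organoid growth rate. Because organoids are
heterogeneous, the package analyses *tracked single organoids*: each
organoid is segmented at every time point, linked into a track, quantified
(24 metabolic and morphological variables), normalized to its own
pretreatment value, and modeled longitudinally.

The package is aimed at microscopy/image-analysis researchers and
organoid-screening labs who want the full chain — registration → ORR →
segmentation → tracking → quantification → statistics — with every stage
testable against a built-in synthetic phantom generator with ground truth
(no microscope data required to validate an installation).

## What is inside

| Stage | Entry points |
|---|---|
| Phantom generation (ground truth) | `phantom_config()`, `generate_phantom_series()`, `treatment_trajectories()`, `write_phantom()` |
| Registration + ORR | `read_well_series()`, `estimate_shift()`, `register_series()`, `compute_orr()` |
| Segmentation (12-step edge-enhancement) | `segmentation_params()`, `segment_frame()`, `split_touching()`, `circularity()`, `dice()` |
| Tracking (two-pass LAP + gap closing) | `extract_centroids()`, `link_tracks()`, `match_tracks_to_truth()` |
| Quantification (24 variables) | `quantify_organoid()`, `build_feature_table()`, `exclude_border_tracks()`, `region_properties()` |
| Longitudinal statistics | `normalize_series()`, `fit_lmm()` (random intercept + AR(1)), `fit_pooled()`, `lsmeans_contrasts()`, `bivariate_fit()`, `correlation_matrix()` |
| Multivariate analysis | `standardize_within_time()`, `fit_pca()`, `pca_project()`, `ellipse_95()`, `top_loadings()` |
| Orchestration | `pipeline_config()`, `run_pipeline()`, `inst/cli/orgredox` |

The longitudinal model is
`Y ~ time + treatment + treatment:time + (1 | organoid)` with categorical
time and AR(1) within-organoid residual correlation (REML via `nlme`),
with estimated-marginal-means Tukey contrasts per time point (`emmeans`).
See the methods vignette (`vignettes/organoid-redox-imaging.Rmd`) for the
model, parameter and design details.

## Worked example

Generate a control-well phantom (8 organoids, 2 px/frame stage drift,
+10% growth at 48 h), run the stages, and recover the growth:

```r
library(orgredox)

cfg <- phantom_config(seed = 7, treatment = "control",
                      n_organoids = 8, drift_px = c(2, 2))
ph  <- generate_phantom_series(cfg)
ph$series
#> well_series 'PH07' (control): 6 frames of 512x512, t = 0, 0.33, 12, 24, 36, 48 h

reg <- register_series(ph$series)
reg$shifts
#>   frame  dy  dx       ncc low_confidence
#> 1     1   0   0 1.0000000          FALSE
#> 2     2  -2  -2 0.9932114          FALSE
#> 3     3  -4  -4 0.9868655          FALSE
#> 4     4  -6  -6 0.9742024          FALSE
#> 5     5  -8  -8 0.9606044          FALSE
#> 6     6 -10 -10 0.9474959          FALSE

masks  <- lapply(reg$series$nadh, segment_frame)
tracks <- link_tracks(lapply(masks, extract_centroids), tracking_params(),
                      times_h = reg$series$times_h)
feats  <- exclude_border_tracks(build_feature_table(tracks, masks, reg$series))
norm   <- normalize_series(feats, "area", mode = "organoid")
aggregate(Y ~ time_h, norm, mean)
#>   time_h      Y
#> 1   0.00 1.0000
#> 2   0.33 1.0012
#> 3  12.00 1.0254
#> 4  24.00 1.0501
#> 5  36.00 1.0758
#> 6  48.00 1.0986

match_tracks_to_truth(tracks, ph$truth$tracks)
#> [1] 1
```

The recovered shifts are exactly the (negated, cumulative) configured
drift; the mean organoid-level normalized area rises to 1.099 at 48 h
(the phantom was configured to grow 10%), and every detection is assigned
to its true organoid identity. `run_pipeline()` packages these stages,
writes CSV artifacts plus a JSON-lines run log, and — when several
treatment groups are present — adds the mixed-model contrasts and PCA
outputs.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "orgredox", package = "orgredox"))')" \
    run --phantom-seed 7 --treatment control --out out_dir
```

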