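# octaquant

Quantification and paired device comparison of 2-D en-face OCT angiography
(OCTA) images, with a ground-truthed synthetic angiogram simulator.

OCTA biomarkers — vessel area density (VAD), total vessel length (TVL),
branch-node count, fractal dimension (FD), median vessel length (MVL), mean
vessel diameter (MVD), and the foveal avascular zone (FAZ) area — are widely
used ischemia markers, but they are sensitive to device-specific background
noise: speckle misclassified as vasculature inflates density and branching
metrics and destabilizes FAZ delineation. `octaquant` implements a unified
analysis pipeline so that two devices imaging the same eyes can be compared
on identical footing:

1. **Segmentation front end** — 2-D Frangi vesselness
   (`exp(−R_B²/2β²)(1 − exp(−S²/2γ²))` over scales 1–3 px) followed by
   windowed two-class fuzzy c-means thresholding (70-px kernel).
2. **Topology** — Zhang–Suen homotopic thinning, diameters as 2 × the
   Euclidean distance transform, skeleton-to-graph conversion with branch
   nodes (≥ 3 neighbours) and 2-px twig pruning.
3. **FAZ** — automatic closing-then-components segmentation with a seeded
   fallback that changes only the initialization.
4. **Quality metrics** — noise-floor SD (sample SD of eroded-FAZ
   intensities), CNR = (ring mean − FAZ mean)/FAZ SD over a 0.5–1.5 mm
   annulus, and the FAZ-noise rate against a pooled 97.5th-percentile
   threshold.
5. **Paired statistics** — two-sided Wilcoxon signed-rank (exact null for
   n ≤ 25, mid-ranks, zeros dropped) and Cliff's delta
   `δ = (n⁺ − n⁻)/n`, with median (IQR) / mean (SD) summaries and a
   Shapiro–Wilk display gate; p-values unadjusted.

Because clinical OCTA images are rarely shareable, the package ships a
phantom generator: a Poisson/Delaunay capillary mesh around an avascular
elliptical FAZ (with the terminal capillary ring that bounds a real FAZ),
rasterized to ground-truth masks and imaged under device-like folded-normal
noise presets (`clean` vs `noisy`, including streaky vessel-scale speckle
grain). Every pipeline stage is tested against these ground truths.

## Worked example

```r
library(octaquant)

cfg <- run_config(spec = image_spec(512), seed = 1)
res <- run_simulate_and_quantify(
  n_participants = 5,                  # 10 eyes, both devices
  model_a = device_preset("clean"),
  model_b = device_preset("noisy"),
  config = cfg
)

dplyr::select(tidy(res$comparison), metric, n, delta, p_value)[c(1, 6, 9, 10), ]
#> # A tibble: 4 × 4
#>   metric             n delta p_value
#>   <chr>          <int> <dbl>   <dbl>
#> 1 vad_pct           10    -1 0.00195
#> 2 mvl_um            10     1 0.00195
#> 3 cnr               10     1 0.00195
#> 4 noise_floor_sd    10    -1 0.00195
```

Reading the rows: with the clean device as reference, the noisy device
reported a *higher* VAD in all 10 eyes (δ = −1: spurious speckle detections
inflate density) and a *lower* median vessel length in all 10 (δ = +1:
fragmented skeletons), while the clean device had higher contrast-to-noise
ratio and lower noise floor in every eye — the characteristic signature of a
noise-dominated device comparison. `autoplot(res$comparison)` draws the
δ dot plot; `res$truth_recovery` reports per-eye VAD and FAZ-area errors
against the simulator's ground truth.

For real images, list them in a manifest CSV (`path, participant, eye,
device, plexus`) and run:

```r
run_quantify("manifest.csv", run_config(), out_dir = "results/")
```

which writes `metrics.csv` (one row per image), `comparison.csv` (one row
per metric) and the configuration used. A helper script
`inst/scripts/octaquant-synth.R` writes phantom cohorts to disk as PNGs with
a manifest and JSON sidecar.

## Vignette

`vignettes/octaquant-methods.Rmd` documents the models, default parameters
(with units and rationale), the simulator's scope and limits, numerical
conventions, and known limitations.
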