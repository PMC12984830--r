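---
title: "Quantifying en-face OCT angiograms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying en-face OCT angiograms: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(octaquant)
```

## The problem

Optical coherence tomography angiography (OCTA) produces 2-D en-face maps of
the perfused retinal microvasculature.  Quantitative biomarkers extracted from
those maps — vessel area density (VAD), total vessel length (TVL), branch-node
counts, fractal dimension (FD), median vessel length (MVL), mean vessel
diameter (MVD), and the area of the foveal avascular zone (FAZ) — are used
clinically for ischemia assessment and longitudinal monitoring.  They are also
notoriously sensitive to image quality: background decorrelation speckle can
be misclassified as vasculature, inflating density and branching metrics and
destabilizing FAZ delineation.  When two devices image the same eyes, the
*pairwise* comparison of biomarkers, together with explicit image-quality
metrics, separates anatomy from device signature.

`octaquant` implements that entire workflow: a segmentation front end, a
skeleton/graph topology layer, FAZ segmentation, the three FAZ-based quality
metrics, and a paired non-parametric comparison layer.  Because clinical OCTA
datasets are rarely shareable, the package also ships a ground-truthed
synthetic angiogram simulator so that every stage is testable end to end.

## Pipeline

### Vessel enhancement

The front end is the classic 2-D Frangi vesselness for bright tubular
structures.  At Gaussian scale $\sigma$, with ordered Hessian eigenvalues
$|\lambda_1| \le |\lambda_2|$,

$$
V_\sigma =
\begin{cases}
0 & \lambda_2 \ge 0\\
\exp\!\left(-\frac{R_B^2}{2\beta^2}\right)
\left(1 - \exp\!\left(-\frac{S^2}{2\gamma^2}\right)\right) & \text{otherwise,}
\end{cases}
\qquad R_B = \frac{\lambda_1}{\lambda_2},\quad S = \sqrt{\lambda_1^2 + \lambda_2^2},
$$

taking the per-pixel maximum over scales and normalizing the map to $[0,1]$.
Defaults: scales $\sigma \in \{1, 2, 3\}$ px — at the standard macular
protocol (3 mm over 512 px, 5.86 µm/px) capillaries span roughly 1–4 px, so
small scales carry all the signal; $\beta = 0.5$ (the conventional blobness
sensitivity); $\gamma$ set per scale to half the maximum structureness
(Frangi's heuristic).  The derivative kernels are explicitly de-meaned so a
constant image has exactly zero response, which also makes the map invariant
to additive intensity offsets.

### Binarization

Vessel/background classification is a windowed two-class fuzzy c-means
(fuzzifier $m = 2$, histogram-accelerated, tolerance $10^{-5}$, centres
initialized at the window extremes).  A pixel is a vessel when its membership
in the brighter class exceeds 0.5; for two classes this reduces to exceeding
the midpoint of the two class centres, with ties falling to background.
Windows are `kernel_px = 70` pixels on a side (adjusted to 71 for symmetry),
placed on a half-window grid, and the class-centre maps are bilinearly
interpolated between window centres — a tractable approximation of a full
sliding window.  Windows whose centres are separated by less than `min_sep =
0.05` carry no contrast of their own (for example windows wholly inside the
FAZ) and inherit centres from the nearest contrast-bearing windows through
the interpolation; if *no* window carries contrast the whole image is
background.

### Skeleton, diameters, graph

The mask is thinned to one-pixel-wide centerlines by the Zhang–Suen
two-subiteration scheme iterated to convergence, followed by a redundant
pixel cleanup that guarantees no fully-set 2×2 block while preserving
connectivity.  Diameters use the 2 × EDT convention: twice the Euclidean
distance from a skeleton pixel to the nearest background pixel (the
alternative 2 × EDT − 1 differs by one pixel; the choice is recorded in the
function documentation so the ±1 px ambiguity is explicit).

Branch pixels are skeleton pixels with ≥ 3 skeleton 8-neighbours; 8-adjacent
branch pixels merge into one node cluster whose coordinate is the rounded
centroid.  Endpoints have exactly one neighbour.  The remaining pixels form
chains traced between nodes; segment length is the sum of inter-pixel steps
(1 orthogonal, √2 diagonal, including the step onto each terminal cluster),
converted to µm.  Pruning removes endpoint-terminated segments shorter than
`twig_px = 2` pixel steps and connected components shorter than the same
threshold, then dissolves nodes left with two incident segments by merging
them (adding the cluster's internal steps; for the typical single-pixel
cluster this is exact).  Pruning is a single pass by default — iterating to a
fixpoint is exposed as `iterate_prune` but off, since a twig threshold of two
pixels converges in one pass on realistic masks.

### FAZ segmentation

The binarized mask is morphologically closed (disk radius 2 px) to seal
inter-capillary gaps; 4-connected background components are labelled and the
component containing the field centre is taken as the FAZ, holes filled, area
= pixel count × pixel area.  When the centre pixel is vascular (noise
contamination), the automatic path returns a failure status and the pipeline
re-runs the *identical* segmentation from a seed point — seeding changes only
the initialization, never the segmentation, and a seed landing on a vessel
pixel is snapped to the nearest background pixel within 10 px, mirroring how
an operator places an approximate initialization contour rather than an
exact point.

### Quality metrics

Three per-image metrics quantify noise with the FAZ as the natural
signal-free region:

* **Noise-floor SD**: the sample (n−1) standard deviation of intensities in
  the FAZ eroded by 2 px (erosion avoids contamination by parafoveal
  capillaries).
* **CNR**: (mean intensity in a 0.5–1.5 mm annulus about the FAZ centroid −
  mean eroded-FAZ intensity) / noise-floor SD.  Scale- and offset-invariant.
* **FAZ-noise rate**: the percentage of eroded-FAZ pixels *strictly* above a
  threshold $T_{FAZ}$, the 97.5th percentile of FAZ intensities pooled over
  all images of the analysis set.  Percentiles use linear interpolation
  between closest ranks, $r = q(n-1)$ on the sorted pool — conventions
  differ, so the rule is fixed package-wide and shared with all IQR
  reporting.  Pooling is per plexus across both devices by default
  (`pooling = "plexus"`); a global scope is available because the original
  pooling scope is ambiguous in this class of analyses.

By construction, if all images shared one noise distribution the cohort-mean
FAZ-noise rate would be 2.5%; deviations between devices measure which
device's background exceeds the common threshold.

### Paired statistics

Each metric is compared across devices eye by eye: a two-sided Wilcoxon
signed-rank test (zero differences dropped, mid-ranks for ties, exact null
distribution for n ≤ 25 computed by expanding the signed-rank generating
function — identical to enumerating all $2^n$ sign assignments — and a
normal approximation with continuity and tie corrections above), and Cliff's
delta for paired data,

$$\delta = \frac{n^+ - n^-}{n} \in [-1, 1],$$

where $n^+$ ($n^-$) counts pairs in which the reference device's value is
larger (smaller).  $\delta = \pm 1$ means complete dominance.  A Shapiro–Wilk
gate selects the summary display only (median/IQR vs mean/SD; FD is always
mean/SD by convention) and never switches the test.  P-values are reported
unadjusted: the endpoints are strongly correlated and the analysis is
effect-size-driven, so a formal multiplicity correction is deliberately not
applied (a caller can `p.adjust` the tidy output if desired).

## The synthetic angiogram simulator

### What it emulates

A capillary mesh on a 3 × 3 mm field around an avascular elliptical FAZ:
interior nodes are Poisson-sampled outside the ellipse at `density = 140`
points/mm², Delaunay-triangulated (`deldir`), and edges are kept when their
length lies in 0.02–0.13 mm and their chord does not cut the ellipse.
Defaults give a truth VAD near 33%, truth TVL near 190 mm, vessel diameters
log-normal around 19 µm, and FAZ area near 0.24 mm² with ±10% per-eye jitter
— all in the range reported for healthy maculae.  A rim of nodes is seeded
just outside the ellipse (offset 0.015 mm): anatomically this is the terminal
capillary ring that bounds a real FAZ, and structurally it guarantees the
mesh contains a closed ring around the FAZ.  Without it, a Delaunay mesh at
realistic density leaves the background 4-connected and *no*
closing-then-components segmentation could bound the FAZ; with it, automatic
FAZ segmentation on clean phantoms recovers the ellipse area to within a few
percent.

Device noise is folded-normal background $|\mathcal{N}(0, \sigma)|$
(nonnegative, like a decorrelation background; SD $= \sigma\sqrt{1 - 2/\pi}$)
plus Gaussian speckle on vessel pixels.  The background field can be
spatially *grained*: smoothed at a correlation scale and rescaled to unit
marginal variance before folding, so every per-pixel statistic is exactly the
white-noise folded normal while the speckle forms grains the size of a
device's point spread function — optionally anisotropic, emulating the
streaky fast-scan-axis decorrelation texture of real devices.  Graining
matters: pixel-independent noise is annihilated by the Frangi scales and can
never be misclassified as vasculature, whereas vessel-scale streaks reproduce
the misclassification mechanism that inflates density metrics on noisy
devices.

### The shipped presets

* `clean`: $\sigma = 5$, vessel mean 200, speckle CV 0.10, isotropic grain
  1.5 px.  Measured: CNR ≈ 20–25, noise-floor SD ≈ 3.
* `noisy`: $\sigma = 100$, vessel mean 150, speckle CV 0.10, grain (0.8, 2.5)
  px.  Measured: CNR ≈ 0.8, noise-floor SD ≈ 60.

The presets are calibrated so the noisy regime reproduces the qualitative
mechanism of a high-noise device — background streaks misclassified as
vessels (VAD and TVL inflated in every paired eye) and fragmented skeletons
(median segment length reduced in every paired eye) — while the clean device
recovers the phantom's truth.  During calibration, regimes with dim vessels
(vessel mean near the noise floor) turned out to *reduce* measured VAD: the
adaptive threshold rises with the noise and thins the vessels faster than
speckle adds area.  The final preset therefore keeps vessels bright and lets
the background streaks do the inflating, consistent with the observation
that high-noise devices report denser, longer, more fragmented networks.
The calibration is the package's own; no claim is made that the presets
reproduce any particular instrument's absolute numbers.

### What it does not emulate

No hemodynamics, no 3-D volume or projection artifacts, no pathology (edema,
non-perfusion), no motion artifacts, no vendor-specific intensity transfer
curves.  Passing tests on phantoms therefore demonstrates the pipeline's
internal correctness and its qualitative noise response, not clinical
equivalence on any real device pair.

### Seeds

All randomness flows from one cohort seed; per-eye and per-device sub-seeds
derive from it by a fixed multiplicative hash of the (participant, eye,
stream) tuple, kept below $2^{31}$.  Regeneration is bit-identical, paired
images share their truth by construction, and the caller's RNG state is
restored after every draw.

## Numerical choices and degenerate inputs

* Percentile/IQR: linear interpolation, $r = q(n-1)$; fixed package-wide.
* FD: box sides in powers of two from 2 px up to a quarter of the image side
  (2–128 px at 512), origin-aligned, least-squares slope of $\log N$ vs
  $\log(1/s)$; a full mask gives exactly 2, a 1-px line 1, the empty mask 0
  with an explicit flag.  FD is computed on the *mask*, not the skeleton —
  reported healthy-macula values near 1.97–1.98 are consistent with
  dense-mask box counting.
* Empty structures propagate missing values (`NA`), never fabricated zeros;
  the single exception is FD's flagged 0 on an empty mask.
* Node counts include branch clusters only, not endpoints; whether published
  node counts include endpoints is generally unstated, so the convention is
  documented rather than assumed.
* MVL denotes the *median* per-segment length; the mean is also computed
  (`mean_vl_um`) since both summaries appear in the literature under similar
  names.
* Degenerate cases: constant images produce empty vesselness maps; empty
  masks produce empty graphs and `NA` metrics; a FAZ too small to survive
  erosion raises an explicit error naming the minimum viable size; identical
  paired values give $p = 1$ with an `all_zero` flag.

## Problem sizes

The test suite exercises the full 512 × 512 protocol on a 25-participant /
50-eye paired cohort (100 quantifications, a few minutes of CPU) and smaller
grids (96–256 px) for orchestration tests where full resolution adds nothing.
The acceptance script regenerates the full cohort from scratch at 512 × 512.

## Known limitations

* Thin (1–2 px) capillaries are partially missed by the front end at 512-px
  sampling, so absolute VAD under-estimates truth by several percentage
  points on clean phantoms; paired comparisons are unaffected because both
  devices share the front end — exactly the argument for unified pipelines
  in cross-device studies.
* The merged-segment length after node dissolution approximates multi-pixel
  clusters by their pixel count; for the dominant single-pixel clusters it
  is exact.
* Two eyes of one participant are treated as independent pairs, mirroring
  common practice in device-comparison studies; a mixed-effects treatment of
  inter-eye correlation is out of scope.
* The Wilcoxon normal approximation is used above n = 25; at the cohort
  sizes here (n = 50) its agreement with reference implementations is tested
  to $10^{-6}$.
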