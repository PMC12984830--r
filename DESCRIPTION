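Package: octaquant
Title: Quantification and Device Comparison of En-Face OCT Angiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end quantification pipeline for 2-D en-face optical
    coherence tomography angiography (OCTA) images: Frangi vesselness
    enhancement, windowed fuzzy c-means binarization, homotopic skeletonization
    with distance-transform diameters, graph conversion with twig pruning,
    vascular biomarkers (vessel area density, total vessel length, node count,
    fractal dimension, median vessel length, mean vessel diameter), automatic
    and seeded segmentation of the foveal avascular zone (FAZ), FAZ-based
    image-quality metrics (FAZ-noise rate against a pooled 97.5th-percentile
    threshold, contrast-to-noise ratio, noise-floor standard deviation), and a
    paired non-parametric device-comparison layer (Wilcoxon signed-rank tests
    and Cliff's delta).  A ground-truthed synthetic angiogram simulator with
    device-like noise presets makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    EBImage,
    deldir,
    igraph,
    png,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
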