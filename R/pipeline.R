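# End-to-end orchestration: per-image quantification, cohort quantification
# with the pooled noise threshold, manifest-driven runs, and the
# simulate-then-quantify driver.  One top-level seed feeds every source of
# randomness; all stages run with identical settings on both devices.

#' Analysis run configuration
#'
#' Collects every tunable of the pipeline in one serializable object:
#' image geometry, segmentation front end, graph pruning, FAZ/quality ROI
#' geometry, the pooled-percentile level and pooling scope, and the seed.
#'
#' @param spec An [image_spec()].
#' @param segmentation From [segmentation_config()].
#' @param twig_px Twig threshold in pixel steps.
#' @param iterate_prune Iterate pruning to a fixpoint? Default FALSE.
#' @param erosion_px FAZ ROI erosion radius (px).
#' @param annulus_inner_mm,annulus_outer_mm Ring ROI radii (mm).
#' @param percentile Pooled noise-threshold percentile, default 0.975.
#' @param pooling `"plexus"` (pool FAZ intensities per plexus across devices)
#'   or `"global"`.
#' @param closing_px FAZ segmentation closing radius (px).
#' @param seed Top-level RNG seed.
#' @return A list of class `octa_config`.
#' @export
run_config <- function(spec = image_spec(), segmentation = segmentation_config(),
                       twig_px = 2, iterate_prune = FALSE, erosion_px = 2L,
                       annulus_inner_mm = 0.5, annulus_outer_mm = 1.5,
                       percentile = 0.975, pooling = c("plexus", "global"),
                       closing_px = 2L, seed = 1L) {
  pooling <- match.arg(pooling)
  structure(
    list(
      spec = spec, segmentation = segmentation, twig_px = twig_px,
      iterate_prune = iterate_prune, erosion_px = as.integer(erosion_px),
      annulus_inner_mm = annulus_inner_mm, annulus_outer_mm = annulus_outer_mm,
      percentile = percentile, pooling = pooling,
      closing_px = as.integer(closing_px), seed = as.integer(seed)
    ),
    class = "octa_config"
  )
}

#' Serialize / restore a run configuration
#'
#' Round-trips an [run_config()] through a YAML key-value file.
#'
#' @param config An `octa_config`.
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   the restored `octa_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "octa_config"))
  x <- unclass(config)
  x$spec <- unclass(x$spec)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sp <- x$spec
  run_config(
    spec = image_spec(sp$width_px, sp$height_px, sp$extent_mm, sp$bit_depth),
    segmentation = segmentation_config(
      scales = as.numeric(x$segmentation$scales),
      beta = x$segmentation$beta,
      kernel_px = x$segmentation$kernel_px,
      min_sep = x$segmentation$min_sep
    ),
    twig_px = x$twig_px, iterate_prune = x$iterate_prune,
    erosion_px = x$erosion_px,
    annulus_inner_mm = x$annulus_inner_mm, annulus_outer_mm = x$annulus_outer_mm,
    percentile = x$percentile, pooling = x$pooling,
    closing_px = x$closing_px, seed = x$seed
  )
}

#' Quantify a single en-face image
#'
#' Runs the full per-image pipeline: binarization, skeletonization, diameter
#' mapping, graph conversion and pruning, vascular metrics, and FAZ
#' segmentation (automatic, falling back to centre-seeded initialization when
#' automatic initialization fails).  Quality metrics that need the pooled
#' threshold are computed at cohort level by [quantify_cohort()].
#'
#' @param image An [en_face_image()].
#' @param config An [run_config()].
#' @param faz_seed Optional `c(row, col)` FAZ initialization.
#' @param keep_objects Also return the intermediate mask/skeleton/graph/FAZ
#'   objects? Default FALSE.
#' @return A one-row tibble of metrics (plus `objects` list-column when
#'   requested).
#' @export
quantify_image <- function(image, config = run_config(), faz_seed = NULL,
                           keep_objects = FALSE) {
  stopifnot(inherits(image, "octa_image"))
  spec <- image$spec
  mask <- binarize_image(image, config$segmentation)
  sk <- skeletonize(mask)
  dm <- diameter_map(mask$mask, sk, spec)
  gr <- build_vessel_graph(sk, dm, spec)
  gr <- prune_graph(gr, twig_px = config$twig_px, iterate = config$iterate_prune)
  faz <- segment_faz(mask, spec, seed_point = faz_seed,
                     closing_px = config$closing_px)
  seeded <- !is.null(faz_seed)
  if (!faz$ok && is.null(faz_seed)) {
    # automatic initialization failed: seed at the field centre, mirroring
    # manual seeding of noise-contaminated scans
    ctr <- c(round(spec$height_px / 2), round(spec$width_px / 2))
    faz <- tryCatch(
      segment_faz(mask, spec, seed_point = ctr, closing_px = config$closing_px),
      error = function(e) faz
    )
    seeded <- TRUE
  }
  sls <- segment_length_stats(gr)
  out <- tibble(
    participant = image$participant, eye = image$eye,
    device = image$device, plexus = image$plexus,
    vad_pct = vessel_area_density(mask),
    faz_area_mm2 = if (faz$ok) faz$area_mm2 else NA_real_,
    faz_seeded = seeded && faz$ok,
    faz_ok = faz$ok,
    tvl_mm = total_vessel_length(gr),
    n_nodes = count_nodes(gr),
    fd = as.numeric(fractal_dimension(mask)),
    mvl_um = unname(sls["median_um"]),
    mean_vl_um = unname(sls["mean_um"]),
    mvd_um = mean_vessel_diameter(dm)
  )
  if (keep_objects) {
    out$objects <- list(list(mask = mask, skeleton = sk, diameters = dm,
                             graph = gr, faz = faz))
  }
  out
}

# Quality-metric pieces that do not need the pooled threshold.
image_quality_parts <- function(image, faz, config) {
  spec <- image$spec
  tryCatch({
    roi <- eroded_faz_roi(faz, erosion_px = config$erosion_px)
    ring <- annulus_roi(faz$centroid, spec,
                        inner_mm = config$annulus_inner_mm,
                        outer_mm = config$annulus_outer_mm)
    ring$mask <- ring$mask & !roi$mask   # enforce disjoint ROIs
    list(
      faz_values = roi_values(image, roi),
      cnr = contrast_to_noise(image, ring, roi),
      noise_floor_sd = noise_floor_sd(image, roi)
    )
  }, error = function(e) {
    list(faz_values = numeric(), cnr = NA_real_, noise_floor_sd = NA_real_)
  })
}

#' Quantify a cohort of images
#'
#' Applies [quantify_image()] to every row of a cohort table with identical
#' settings, then computes the quality metrics: eroded-FAZ intensities are
#' pooled over all images of the analysis set (per plexus by default, or
#' globally) into the 97.5th-percentile noise threshold, from which each
#' image's FAZ-noise rate is derived, along with its CNR and noise-floor SD.
#'
#' @param cohort A tibble with columns `participant`, `eye`, `device`,
#'   `plexus` and an `image` list-column of [en_face_image()] objects (e.g.
#'   from [generate_paired_cohort()] or [read_manifest()]).
#' @param config An [run_config()].
#' @param progress Print per-image progress? Default FALSE.
#' @return A metrics tibble, one row per image, with vascular and quality
#'   metrics and the pooled threshold used (`t_faz_used`).
#' @export
quantify_cohort <- function(cohort, config = run_config(), progress = FALSE) {
  stopifnot(is.data.frame(cohort), "image" %in% names(cohort))
  rows <- vector("list", nrow(cohort))
  qparts <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    img <- cohort$image[[i]]
    met <- quantify_image(img, config, keep_objects = TRUE)
    objs <- met$objects[[1]]
    met$objects <- NULL
    qparts[[i]] <- image_quality_parts(img, objs$faz, config)
    rows[[i]] <- met
    if (progress) {
      inform(sprintf("[%d/%d] %s %s %s", i, nrow(cohort),
                     met$participant, met$eye, met$device))
    }
  }
  metrics <- bind_rows(rows)
  metrics$cnr <- vapply(qparts, function(q) q$cnr, 1)
  metrics$noise_floor_sd <- vapply(qparts, function(q) q$noise_floor_sd, 1)
  # pooled threshold and FAZ-noise rate
  metrics$faz_noise_rate_pct <- NA_real_
  metrics$t_faz_used <- NA_real_
  groups <- if (config$pooling == "plexus") unique(metrics$plexus) else "all"
  for (g in groups) {
    sel <- if (config$pooling == "plexus") metrics$plexus == g else
      rep(TRUE, nrow(metrics))
    pool <- unlist(lapply(qparts[sel], function(q) q$faz_values))
    if (length(pool) == 0L) next
    t_faz <- pooled_noise_threshold(pool, q = config$percentile)
    idx <- which(sel)
    for (i in idx) {
      v <- qparts[[i]]$faz_values
      if (length(v)) {
        metrics$faz_noise_rate_pct[i] <- 100 * sum(v > t_faz) / length(v)
      }
    }
    metrics$t_faz_used[idx] <- t_faz
  }
  metrics
}

#' Read a cohort manifest
#'
#' A manifest CSV lists one image per row with columns `path`, `participant`,
#' `eye`, `device`, `plexus`; images are loaded with [read_enface()] against
#' the config's spec.
#'
#' @param path Manifest CSV path.
#' @param config An [run_config()] (for the image spec).
#' @return A cohort tibble suitable for [quantify_cohort()].
#' @export
read_manifest <- function(path, config = run_config()) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "participant", "eye", "device", "plexus")
  if (!all(need %in% names(mf))) {
    abort(sprintf("manifest must have columns: %s", paste(need, collapse = ", ")))
  }
  base <- dirname(path)
  mf$image <- lapply(seq_len(nrow(mf)), function(i) {
    p <- mf$path[i]
    if (!file.exists(p)) p <- file.path(base, mf$path[i])
    read_enface(p, config$spec, mf$plexus[i], mf$device[i],
                mf$participant[i], mf$eye[i])
  })
  as_tibble(mf[c("participant", "eye", "device", "plexus", "image")])
}

#' Quantify a cohort from a manifest and write all outputs
#'
#' The full analysis entry point for real images: reads the manifest,
#' quantifies every image with identical settings, builds the paired
#' device-comparison table, and writes `metrics.csv`, `comparison.csv` and a
#' parameter log to `out_dir`.  Eyes missing one device are kept in the
#' per-image outputs and excluded from paired statistics.
#'
#' @param manifest Path to the manifest CSV.
#' @param config An [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param reference Reference device label for Cliff's delta; defaults to the
#'   first device in the manifest.
#' @return Invisibly, a list with `metrics` and `comparison` tibbles.
#' @export
run_quantify <- function(manifest, config = run_config(), out_dir = ".",
                         reference = NULL) {
  cohort <- read_manifest(manifest, config)
  metrics <- quantify_cohort(cohort, config)
  reference <- reference %||% cohort$device[[1]]
  comparison <- if (length(unique(cohort$device)) == 2L) {
    compare_devices(metrics, reference = reference)
  } else {
    warn("manifest does not contain exactly two devices: comparison skipped.")
    NULL
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(comparison)) {
    utils::write.csv(as.data.frame(comparison),
                     file.path(out_dir, "comparison.csv"), row.names = FALSE)
  }
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(list(metrics = metrics, comparison = comparison))
}

#' Simulate a paired cohort and quantify it end to end
#'
#' Generates a two-device phantom cohort, quantifies both devices' images
#' with identical settings, builds the comparison table with device A as the
#' reference, and reports ground-truth recovery (per-eye VAD and FAZ-area
#' errors against the simulator's truth).
#'
#' @param n_participants Number of participants (two eyes each).
#' @param model_a,model_b Device noise models (defaults: clean vs noisy
#'   presets).
#' @param config An [run_config()]; its seed drives the simulation.
#' @param network_params From [cohort_network_params()].
#' @param progress Print progress? Default FALSE.
#' @return A list with `metrics`, `comparison`, `truth_recovery`, and
#'   `cohort_truth` (per-eye truth summaries).
#' @export
run_simulate_and_quantify <- function(n_participants = 25,
                                      model_a = device_preset("clean"),
                                      model_b = device_preset("noisy"),
                                      config = run_config(),
                                      network_params = cohort_network_params(),
                                      progress = FALSE) {
  cohort <- generate_paired_cohort(
    n_participants, model_a, model_b,
    spec = config$spec, network_params = network_params, seed = config$seed
  )
  metrics <- quantify_cohort(cohort, config, progress = progress)
  comparison <- compare_devices(metrics, reference = "A")
  truth <- cohort %>%
    dplyr::distinct(.data$participant, .data$eye, .keep_all = TRUE) %>%
    select("participant", "eye", "vad_truth_pct", "faz")
  truth$faz_area_truth_mm2 <- vapply(
    truth$faz, function(f) pi * f$a * f$b, 1
  )
  truth$faz <- NULL
  recovery <- metrics %>%
    left_join(truth, by = c("participant", "eye")) %>%
    mutate(
      vad_error_pp = .data$vad_pct - .data$vad_truth_pct,
      faz_area_rel_error = (.data$faz_area_mm2 - .data$faz_area_truth_mm2) /
        .data$faz_area_truth_mm2
    ) %>%
    select("participant", "eye", "device", "vad_error_pp", "faz_area_rel_error")
  list(
    metrics = metrics, comparison = comparison,
    truth_recovery = recovery, cohort_truth = truth
  )
}
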