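# Per-image vascular biomarkers: density, length, branching, fractal
# dimension, and FAZ segmentation with seeded fallback.

as_mask_matrix <- function(mask) {
  m <- if (inherits(mask, "octa_mask")) mask$mask else mask
  if (!is.matrix(m)) abort("expected an octa_mask or a matrix.")
  m != 0
}

#' Vessel area density (VAD)
#'
#' Percentage of image pixels classified as perfused vessel.
#'
#' @param mask Binary vessel mask (`octa_mask` or matrix).
#' @return Percent in `[0, 100]`.
#' @export
vessel_area_density <- function(mask) {
  m <- as_mask_matrix(mask)
  100 * sum(m) / length(m)
}

#' Total vessel length (TVL)
#'
#' Sum of all pruned segment lengths, in millimetres.
#'
#' @param graph An `octa_graph` (normally pruned).
#' @return Length in mm (0 for an empty graph).
#' @export
total_vessel_length <- function(graph) {
  stopifnot(inherits(graph, "octa_graph"))
  sum(graph$segments$length_um) / 1000
}

#' Number of branch nodes
#'
#' Counts branch-point clusters (degree >= 3 junctions).  Endpoints are not
#' counted.
#'
#' @inheritParams total_vessel_length
#' @return Integer count.
#' @export
count_nodes <- function(graph) {
  stopifnot(inherits(graph, "octa_graph"))
  nrow(graph$nodes)
}

#' Median and mean vessel segment length
#'
#' Per-segment length statistics in micrometres; the median is the MVL
#' biomarker.  Undefined (NA) for an empty graph.
#'
#' @inheritParams total_vessel_length
#' @return Named numeric vector `c(median_um, mean_um)`.
#' @export
segment_length_stats <- function(graph) {
  stopifnot(inherits(graph, "octa_graph"))
  if (nrow(graph$segments) == 0L) {
    return(c(median_um = NA_real_, mean_um = NA_real_))
  }
  len <- graph$segments$length_um
  c(median_um = quantile_linear(len, 0.5), mean_um = mean(len))
}

#' Mean vessel diameter (MVD)
#'
#' Mean of the per-skeleton-pixel diameters in micrometres; NA for an empty
#' skeleton.
#'
#' @param dmap An [diameter_map()] result.
#' @return Mean diameter in um.
#' @export
mean_vessel_diameter <- function(dmap) {
  stopifnot(inherits(dmap, "octa_diameters"))
  if (!any(dmap$skeleton)) return(NA_real_)
  mean(dmap$um[dmap$skeleton])
}

#' Box-counting fractal dimension
#'
#' Minkowski-Bouligand dimension estimated from occupied-box counts `N(s)` on
#' origin-aligned grids of side `s` in powers of two (2 to 128 px by default,
#' capped at a quarter of the image side), as the least-squares slope of
#' `log N(s)` against `log(1/s)`.  A full mask gives exactly 2, a straight
#' line about 1, and the empty mask is reported as 0 with a flag attribute.
#'
#' @param mask Binary mask.
#' @param sizes Box sides in pixels; defaults to powers of two.
#' @return Fractal dimension (attribute `empty` = TRUE when the mask had no
#'   set pixel).
#' @export
fractal_dimension <- function(mask, sizes = NULL) {
  m <- as_mask_matrix(mask)
  if (!any(m)) return(structure(0, empty = TRUE))
  if (is.null(sizes)) {
    sizes <- 2^(1:7)
    sizes <- sizes[sizes <= min(dim(m)) / 4]
  }
  if (length(sizes) < 2L) abort("need at least two box sizes.")
  counts <- vapply(sizes, function(s) {
    nr <- ceiling(nrow(m) / s)
    nc <- ceiling(ncol(m) / s)
    br <- ceiling(row(m) / s)
    bc <- ceiling(col(m) / s)
    length(unique((br[m] - 1L) * nc + bc[m]))
  }, 1L)
  x <- log(1 / sizes)
  y <- log(counts)
  # least-squares slope
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Segment the foveal avascular zone
#'
#' The binarized mask is morphologically closed (disk of radius
#' `closing_px`) to seal inter-capillary gaps; 4-connected components of the
#' remaining background are extracted and the component containing the field
#' centre (or the supplied seed point) is taken as the FAZ, with holes filled.
#' Seeding changes only the initialization, not the segmentation itself.  A
#' seed landing on a vessel pixel after closing is snapped to the nearest
#' background pixel within `snap_px`; if the centre pixel is vascular and no
#' seed is given, a failure status is returned so the caller can seed
#' (mirroring manual initialization of noise-contaminated scans).
#'
#' @param mask Binary vessel mask.
#' @param spec An [image_spec()].
#' @param seed_point Optional `c(row, col)` initialization inside the FAZ.
#' @param closing_px Closing disk radius in px (default 2).
#' @param snap_px Search radius for snapping a seed off a vessel pixel.
#' @return An object of class `octa_faz`: `mask` (logical), `area_mm2`,
#'   `seeded`, `seed_point`, `ok` (FALSE when initialization failed),
#'   `centroid` (row, col).
#' @export
segment_faz <- function(mask, spec = image_spec(), seed_point = NULL,
                        closing_px = 2L, snap_px = 10L) {
  m <- as_mask_matrix(mask)
  fail <- function(msg) {
    structure(
      list(
        mask = matrix(FALSE, nrow(m), ncol(m)), area_mm2 = NA_real_,
        seeded = !is.null(seed_point), seed_point = seed_point,
        ok = FALSE, status = msg, centroid = c(NA_real_, NA_real_)
      ),
      class = "octa_faz"
    )
  }
  closed <- if (closing_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_px) + 1L, shape = "disc")
    cl <- EBImage::closing(matrix(as.integer(m), nrow(m), ncol(m)), brush)
    matrix(as.integer(cl), nrow(m), ncol(m)) > 0L
  } else {
    m
  }
  bg <- !closed
  if (!any(bg)) return(fail("no background after closing"))
  start <- if (is.null(seed_point)) {
    c(round(nrow(m) / 2), round(ncol(m) / 2))
  } else {
    round(seed_point)
  }
  if (!bg[start[1], start[2]]) {
    if (is.null(seed_point)) {
      return(fail("field centre lies on a vessel pixel; supply a seed point"))
    }
    # snap an approximate seed to the nearest background pixel
    cand <- which(bg)
    rr <- (cand - 1L) %% nrow(m) + 1L
    cc <- (cand - 1L) %/% nrow(m) + 1L
    d2 <- (rr - start[1])^2 + (cc - start[2])^2
    if (min(d2) > snap_px^2) {
      abort("seed point lies on a vessel pixel with no background within reach.")
    }
    k <- which.min(d2)
    start <- c(rr[k], cc[k])
  }
  lab <- label_components(matrix(as.integer(bg), nrow(m), ncol(m)), 4L)
  faz <- lab == lab[start[1], start[2]]
  faz <- fill_holes(faz)
  idx <- which(faz)
  structure(
    list(
      mask = faz,
      area_mm2 = length(idx) * spec$pixel_size_mm^2,
      seeded = !is.null(seed_point), seed_point = seed_point,
      ok = TRUE, status = "ok",
      centroid = c(
        mean((idx - 1L) %% nrow(m) + 1L),
        mean((idx - 1L) %/% nrow(m) + 1L)
      )
    ),
    class = "octa_faz"
  )
}

#' @export
print.octa_faz <- function(x, ...) {
  if (x$ok) {
    cat(sprintf(
      "<octa_faz> area %.4f mm2 (%s)\n", x$area_mm2,
      if (x$seeded) "seeded" else "automatic"
    ))
  } else {
    cat(sprintf("<octa_faz> segmentation failed: %s\n", x$status))
  }
  invisible(x)
}
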