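# FAZ-based image-quality metrics: eroded-FAZ and annulus ROIs, the pooled
# 97.5th-percentile noise threshold, FAZ-noise rate, CNR and noise-floor SD.

#' Eroded FAZ region of interest
#'
#' Erodes the FAZ mask by a disk of radius `erosion_px` (default 2) so that
#' parafoveal capillaries cannot contaminate the noise statistics.  An
#' alternative mode replaces the mask by its largest inscribed ellipse
#' (centred on the distance-transform maximum, oriented by second moments,
#' shrunk until fully inside) before eroding, for parity with manual
#' ellipsoid delineation.
#'
#' @param faz An `octa_faz` from [segment_faz()], or a logical mask.
#' @param erosion_px Erosion radius in pixels.
#' @param use_inscribed_ellipse Replace the mask by its inscribed ellipse
#'   first? Default `FALSE`.
#' @return An object of class `octa_roi` (`mask`, `kind`, `geometry`).
#' @export
eroded_faz_roi <- function(faz, erosion_px = 2L, use_inscribed_ellipse = FALSE) {
  m <- if (inherits(faz, "octa_faz")) faz$mask else faz != 0
  if (!any(m)) abort("empty FAZ: cannot build an ROI.")
  geom <- NULL
  if (use_inscribed_ellipse) {
    ell <- inscribed_ellipse(m)
    m <- ell$mask
    geom <- ell$params
  }
  if (erosion_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(erosion_px) + 1L, shape = "disc")
    er <- EBImage::erode(matrix(as.integer(m), nrow(m), ncol(m)), brush)
    m <- matrix(as.integer(er), nrow(m), ncol(m)) > 0L
  }
  if (!any(m)) {
    abort(sprintf(
      "erosion by %d px emptied the FAZ ROI; the FAZ must exceed %d px across.",
      erosion_px, 2 * erosion_px + 1
    ))
  }
  structure(
    list(mask = m, kind = "eroded_faz",
         geometry = c(list(erosion_px = erosion_px), geom)),
    class = "octa_roi"
  )
}

# Largest inscribed ellipse of a mask: centre at the EDT maximum, orientation
# and axis ratio from second moments, scaled until fully contained.
inscribed_ellipse <- function(m) {
  edt <- EBImage::distmap(matrix(as.integer(m), nrow(m), ncol(m)))
  edt <- matrix(as.numeric(edt), nrow(m), ncol(m))
  p0 <- which.max(edt)
  r0 <- (p0 - 1L) %% nrow(m) + 1L
  c0 <- (p0 - 1L) %/% nrow(m) + 1L
  idx <- which(m)
  rr <- (idx - 1L) %% nrow(m) + 1L - r0
  cc <- (idx - 1L) %/% nrow(m) + 1L - c0
  cov <- cov(cbind(cc, rr))
  eg <- eigen(cov, symmetric = TRUE)
  ratio <- sqrt(max(eg$values[2], 1e-9) / eg$values[1])
  theta <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  rmax <- edt[p0]
  grid_r <- row(m) - r0
  grid_c <- col(m) - c0
  xr <- grid_c * cos(theta) + grid_r * sin(theta)
  yr <- -grid_c * sin(theta) + grid_r * cos(theta)
  a <- rmax / max(ratio, 1e-9)  # long axis candidate
  repeat {
    ell <- (xr / a)^2 + (yr / (a * ratio))^2 <= 1
    if (all(m[ell]) || a < 1) break
    a <- a * 0.95
  }
  list(mask = ell & m | ell, params = list(
    centre = c(r0, c0), a_px = a, b_px = a * ratio, theta = theta
  ))
}

#' Annular perfused-signal region of interest
#'
#' Pixels whose centre lies between `inner_mm` and `outer_mm` from the given
#' centre (in physical units), clipped to the field.  The default centre is
#' the FAZ centroid; a manually marked foveal centre may be passed instead.
#'
#' @param centre `c(row, col)` pixel coordinates of the fovea (e.g. the FAZ
#'   centroid).
#' @param spec An [image_spec()].
#' @param inner_mm,outer_mm Annulus radii in mm (0 < inner < outer).
#' @return An `octa_roi` with `kind = "annulus"`.
#' @export
annulus_roi <- function(centre, spec = image_spec(), inner_mm = 0.5, outer_mm = 1.5) {
  if (!(inner_mm > 0 && inner_mm < outer_mm)) {
    abort("need 0 < inner_mm < outer_mm.")
  }
  px <- spec$pixel_size_mm
  nr <- spec$height_px
  nc <- spec$width_px
  dr <- (row(matrix(0, nr, nc)) - centre[1]) * px
  dc <- (col(matrix(0, nr, nc)) - centre[2]) * px
  r <- sqrt(dr^2 + dc^2)
  m <- r >= inner_mm & r <= outer_mm
  if (!any(m)) abort("annulus lies entirely outside the field.")
  structure(
    list(mask = m, kind = "annulus",
         geometry = list(centre = centre, inner_mm = inner_mm, outer_mm = outer_mm)),
    class = "octa_roi"
  )
}

#' Pooled noise threshold from FAZ intensities
#'
#' The 97.5th percentile (by default) of the FAZ intensity distribution pooled
#' over all images and devices of the analysis set, computed by linear
#' interpolation between closest ranks (`r = q (n - 1)` on the sorted pool).
#'
#' @param faz_samples Numeric vector of pooled eroded-FAZ pixel intensities.
#' @param q Percentile in `(0, 1)`, default 0.975.
#' @return The threshold `T_FAZ`.
#' @export
#' @examples
#' pooled_noise_threshold(1:40)  # rank 38.025 -> 39.025
pooled_noise_threshold <- function(faz_samples, q = 0.975) {
  if (length(faz_samples) == 0L) abort("empty intensity pool.")
  if (length(faz_samples) < 40L) {
    warn("fewer than 40 pooled samples: the 97.5th percentile is unstable.")
  }
  quantile_linear(faz_samples, q)
}

roi_values <- function(image, roi) {
  px <- if (inherits(image, "octa_image")) image$pixels else image
  px[roi$mask]
}

#' FAZ-noise rate
#'
#' Percentage of eroded-FAZ pixels whose intensity strictly exceeds the pooled
#' threshold; ties at the threshold do not count.
#'
#' @param image An `octa_image` or matrix.
#' @param roi The eroded-FAZ `octa_roi`.
#' @param t_faz Pooled threshold from [pooled_noise_threshold()].
#' @return Percent in `[0, 100]`.
#' @export
faz_noise_rate <- function(image, roi, t_faz) {
  v <- roi_values(image, roi)
  if (length(v) == 0L) abort("empty ROI.")
  100 * sum(v > t_faz) / length(v)
}

#' Contrast-to-noise ratio
#'
#' `(mean ring intensity - mean FAZ intensity) / FAZ intensity SD`, using the
#' sample (n-1) standard deviation.  Negative values are possible; a constant
#' FAZ makes the ratio undefined and raises an error.
#'
#' @param image An `octa_image` or matrix.
#' @param ring Annulus `octa_roi`.
#' @param faz_roi Eroded-FAZ `octa_roi`.
#' @return The CNR.
#' @export
contrast_to_noise <- function(image, ring, faz_roi) {
  vr <- roi_values(image, ring)
  vf <- roi_values(image, faz_roi)
  if (length(vr) == 0L || length(vf) == 0L) abort("empty ROI.")
  if (any(ring$mask & faz_roi$mask)) abort("ring and FAZ ROIs must be disjoint.")
  s <- sd(vf)
  if (!is.finite(s) || s == 0) abort("constant FAZ intensities: CNR undefined.")
  (mean(vr) - mean(vf)) / s
}

#' Noise-floor standard deviation
#'
#' Sample standard deviation (n-1 denominator) of the eroded-FAZ pixel
#' intensities, in native intensity units.
#'
#' @inheritParams contrast_to_noise
#' @return Nonnegative SD.
#' @export
noise_floor_sd <- function(image, faz_roi) {
  v <- roi_values(image, faz_roi)
  if (length(v) < 2L) abort("need at least 2 ROI pixels for a standard deviation.")
  sd(v)
}
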