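# Synthetic en-face angiogram phantoms: a Poisson/Delaunay capillary mesh
# around an avascular elliptical FAZ, rasterized to ground-truth masks, with
# device-like additive/multiplicative noise.  Every downstream stage of the
# pipeline is testable against these ground truths.

#' Device-like noise model
#'
#' Background noise is folded normal (`|N(0, sigma)|`) everywhere —
#' nonnegative like a decorrelation background, with SD
#' `sigma * sqrt(1 - 2/pi)`; perfused pixels additionally carry their mean
#' intensity and multiplicative speckle `N(0, cv * vessel_mean)`.
#'
#' `grain_px` sets the spatial correlation length of the background speckle:
#' the Gaussian field is smoothed at that scale and rescaled to unit marginal
#' variance before folding, so each pixel's marginal distribution — and hence
#' every noise-floor statistic — is exactly the same folded normal as with
#' white noise, but the speckle forms grains the size of a device's point
#' spread function rather than independent pixels.  Real decorrelation
#' speckle is grained, and grained background is what a vesselness filter can
#' mistake for capillaries; `grain_px = 0` gives pixel-independent noise.
#'
#' @param background_sigma Scale of the folded-normal background (intensity
#'   units), >= 0.
#' @param vessel_mean Mean perfused-pixel intensity, in `(0, max]` for the bit
#'   depth.
#' @param speckle_cv Speckle coefficient of variation on vessel pixels, >= 0.
#' @param grain_px Gaussian correlation scale of the background speckle in
#'   pixels: a single value for isotropic grain, or `c(vertical, horizontal)`
#'   for streaky speckle elongated along the fast-scan axis (0 = white
#'   noise).
#' @param seed RNG seed for [apply_device_noise()].
#' @param bit_depth Intensity bit depth the model targets.
#' @return An object of class `octa_noise_model`.
#' @export
noise_model <- function(background_sigma, vessel_mean, speckle_cv = 0.1,
                        grain_px = 0, seed = 1L, bit_depth = 8L) {
  if (background_sigma < 0) abort("`background_sigma` must be >= 0.")
  if (vessel_mean <= 0 || vessel_mean > 2^bit_depth - 1) {
    abort("`vessel_mean` must be positive and within the bit-depth range.")
  }
  if (speckle_cv < 0) abort("`speckle_cv` must be >= 0.")
  if (any(grain_px < 0) || !length(grain_px) %in% 1:2) {
    abort("`grain_px` must be one or two nonnegative values.")
  }
  if (length(grain_px) == 1L) grain_px <- c(grain_px, grain_px)
  structure(
    list(
      background_sigma = background_sigma, vessel_mean = vessel_mean,
      speckle_cv = speckle_cv, grain_px = grain_px, seed = as.integer(seed),
      bit_depth = as.integer(bit_depth)
    ),
    class = "octa_noise_model"
  )
}

#' Shipped device noise presets
#'
#' `"clean"` emulates a low-noise, high-contrast device (background sigma 5,
#' bright vessels, CNR well above 10, noise-floor SD near 3); `"noisy"` a
#' device whose streaky background speckle sits close to the vessel signal
#' (background sigma 100, CNR near 0.8, noise-floor SD near 60), strong enough
#' that spurious vessel detections and skeleton fragmentation dominate the
#' paired comparison.  The presets are an approximate calibration of the two
#' noise regimes, not measured device characteristics.
#'
#' @param name `"clean"` or `"noisy"`.
#' @param seed Seed stored in the model.
#' @return An [noise_model()].
#' @export
device_preset <- function(name = c("clean", "noisy"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    clean = noise_model(5, 200, speckle_cv = 0.10, grain_px = 1.5, seed = seed),
    noisy = noise_model(100, 150, speckle_cv = 0.10, grain_px = c(0.8, 2.5), seed = seed)
  )
}

#' Generate a synthetic capillary network
#'
#' Poisson-samples interior nodes outside the FAZ ellipse, adds a rim of
#' nodes just outside the ellipse (the terminal capillary ring that bounds a
#' real FAZ), Delaunay-triangulates all nodes, and keeps triangulation edges
#' whose length falls within `edge_len_range` and which do not cut into the
#' ellipse.  Consecutive rim nodes are always connected, so the surviving
#' mesh contains a closed ring around the FAZ.  Per-edge vessel diameters are
#' drawn log-normal.  Deterministic under `seed`.
#'
#' @param spec An [image_spec()].
#' @param density Interior node intensity, points per mm^2 (0 gives an empty
#'   network with a warning flag).
#' @param faz_semi_axes `c(a, b)` ellipse semi-axes in mm, each below half
#'   the field extent.
#' @param faz_rotation Ellipse rotation in radians.
#' @param edge_len_range `c(min, max)` admissible edge lengths in mm.
#' @param diameter_lognorm `c(meanlog, sdlog)` of the log-normal diameter
#'   distribution (diameter in mm).
#' @param seed RNG seed.
#' @param rim_offset_mm Radial clearance of the rim nodes from the ellipse;
#'   default 0.015 mm (about 2.5 px at 512 px / 3 mm).
#' @return An object of class `octa_network`: `edges` tibble
#'   (`x1, y1, x2, y2, radius_mm`, mm coordinates), `faz` (centre, `a`, `b`,
#'   `rot`), `extent_mm`, `empty`, `seed`.
#' @export
generate_vessel_network <- function(spec = image_spec(), density = 140,
                                    faz_semi_axes = c(0.30, 0.25),
                                    faz_rotation = 0,
                                    edge_len_range = c(0.02, 0.13),
                                    diameter_lognorm = c(log(0.019), 0.18),
                                    seed = 1L, rim_offset_mm = NULL) {
  ext <- spec$extent_mm
  if (any(faz_semi_axes >= ext / 2)) abort("FAZ semi-axes must be below half the extent.")
  if (density < 0) abort("`density` must be >= 0.")
  if (is.null(rim_offset_mm)) rim_offset_mm <- 0.015
  a <- faz_semi_axes[1]
  b <- faz_semi_axes[2]
  ctr <- c(ext / 2, ext / 2)
  faz <- list(centre = ctr, a = a, b = b, rot = faz_rotation)
  empty_net <- function() {
    structure(
      list(
        edges = tibble(
          x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
          radius_mm = numeric(), rim = logical()
        ),
        faz = faz, extent_mm = ext, empty = TRUE, seed = as.integer(seed)
      ),
      class = "octa_network"
    )
  }
  if (density == 0) {
    warn("density 0: returning an empty network.")
    return(empty_net())
  }
  with_seed(seed, {
    in_ellipse <- function(x, y, scale = 1) {
      xr <- (x - ctr[1]) * cos(faz_rotation) + (y - ctr[2]) * sin(faz_rotation)
      yr <- -(x - ctr[1]) * sin(faz_rotation) + (y - ctr[2]) * cos(faz_rotation)
      (xr / (a * scale))^2 + (yr / (b * scale))^2 < 1
    }
    n_pts <- stats::rpois(1, density * ext^2)
    px <- stats::runif(n_pts, 0, ext)
    py <- stats::runif(n_pts, 0, ext)
    keep <- !in_ellipse(px, py, scale = 1 + rim_offset_mm / min(a, b))
    px <- px[keep]
    py <- py[keep]
    # rim nodes on the dilated ellipse, spaced like the interior mesh
    spacing <- 0.85 / sqrt(density)
    per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))  # Ramanujan
    n_rim <- max(8L, round(per / spacing))
    th <- seq(0, 2 * pi, length.out = n_rim + 1L)[-(n_rim + 1L)]
    th <- th + stats::runif(1, 0, 2 * pi / n_rim)
    ex <- (a + rim_offset_mm) * cos(th)
    ey <- (b + rim_offset_mm) * sin(th)
    rx <- ctr[1] + ex * cos(faz_rotation) - ey * sin(faz_rotation)
    ry <- ctr[2] + ex * sin(faz_rotation) + ey * cos(faz_rotation)
    x <- c(rx, px)
    y <- c(ry, py)
    rim_id <- seq_len(n_rim)
    if (length(x) < 3L) {
      warn("too few nodes survive: returning an empty network.")
      return(empty_net())
    }
    dd <- deldir::deldir(x, y, suppressMsge = TRUE)
    sg <- dd$delsgs
    len <- sqrt((sg$x2 - sg$x1)^2 + (sg$y2 - sg$y1)^2)
    is_rim_pair <- sg$ind1 <= n_rim & sg$ind2 <= n_rim &
      (abs(sg$ind1 - sg$ind2) == 1L | abs(sg$ind1 - sg$ind2) == n_rim - 1L)
    ok_len <- (len >= edge_len_range[1] & len <= edge_len_range[2]) | is_rim_pair
    # drop edges whose chord cuts into the ellipse
    cuts <- chord_cuts_ellipse(
      sg$x1, sg$y1, sg$x2, sg$y2, ctr, a, b, faz_rotation
    )
    keep <- ok_len & !cuts
    sg <- sg[keep, , drop = FALSE]
    if (nrow(sg) == 0L) {
      warn("no edges survive the length/FAZ filters: returning an empty network.")
      return(empty_net())
    }
    diam <- stats::rlnorm(nrow(sg), diameter_lognorm[1], diameter_lognorm[2])
    structure(
      list(
        edges = tibble(
          x1 = sg$x1, y1 = sg$y1, x2 = sg$x2, y2 = sg$y2,
          radius_mm = diam / 2, rim = is_rim_pair[keep]
        ),
        faz = faz, extent_mm = ext, empty = FALSE, seed = as.integer(seed)
      ),
      class = "octa_network"
    )
  })
}

# Does the open chord (x1,y1)-(x2,y2) intersect the ellipse interior?
# Transform to the frame where the ellipse is the unit circle, then test the
# minimum distance from the origin to the segment.
chord_cuts_ellipse <- function(x1, y1, x2, y2, ctr, a, b, rot) {
  tf <- function(x, y) {
    xr <- (x - ctr[1]) * cos(rot) + (y - ctr[2]) * sin(rot)
    yr <- -(x - ctr[1]) * sin(rot) + (y - ctr[2]) * cos(rot)
    cbind(xr / a, yr / b)
  }
  p <- tf(x1, y1)
  q <- tf(x2, y2)
  vx <- q[, 1] - p[, 1]
  vy <- q[, 2] - p[, 2]
  t <- -(p[, 1] * vx + p[, 2] * vy) / pmax(vx^2 + vy^2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  cx <- p[, 1] + t * vx
  cy <- p[, 2] + t * vy
  cx^2 + cy^2 < 1
}

#' Rasterize a network to ground-truth masks
#'
#' Produces the truth vessel mask (pixels within each edge's radius of its
#' centerline, disc-capped), the Bresenham centerline raster, the FAZ ellipse
#' mask, and a clean image (`vessel_mean` on vessel pixels, 0 elsewhere).
#' Vessel and FAZ masks are exclusive by construction: any stroke bleeding
#' into the ellipse is cleared, as the zone is avascular by definition.
#'
#' @param network An [generate_vessel_network()] result.
#' @param spec The [image_spec()] to rasterize onto; extent must match.
#' @param vessel_mean Intensity of vessel pixels in the clean image.
#' @return A list with `truth_mask`, `truth_skeleton`, `truth_faz_mask`
#'   (logical matrices), `clean_image` (numeric matrix), and `vad_truth_pct`.
#' @export
rasterize_network <- function(network, spec = image_spec(), vessel_mean = 1) {
  stopifnot(inherits(network, "octa_network"))
  if (abs(network$extent_mm - spec$extent_mm) > 1e-9) {
    abort("network and spec extents differ.")
  }
  nr <- spec$height_px
  nc <- spec$width_px
  psz <- spec$pixel_size_mm
  mask <- matrix(FALSE, nr, nc)
  skel <- matrix(FALSE, nr, nc)
  to_col <- function(x) pmin(pmax(ceiling(x / psz), 1L), nc)
  to_row <- function(y) pmin(pmax(ceiling(y / psz), 1L), nr)
  if (!network$empty && nrow(network$edges)) {
    ed <- network$edges
    for (i in seq_len(nrow(ed))) {
      r_px <- ed$radius_mm[i] / psz
      c1 <- ed$x1[i] / psz
      r1 <- ed$y1[i] / psz
      c2 <- ed$x2[i] / psz
      r2 <- ed$y2[i] / psz
      lo_r <- max(1L, floor(min(r1, r2) - r_px))
      hi_r <- min(nr, ceiling(max(r1, r2) + r_px))
      lo_c <- max(1L, floor(min(c1, c2) - r_px))
      hi_c <- min(nc, ceiling(max(c1, c2) + r_px))
      if (lo_r > hi_r || lo_c > hi_c) next
      rows <- lo_r:hi_r
      cols <- lo_c:hi_c
      # pixel centres in px units
      pr <- matrix(rows - 0.5, length(rows), length(cols))
      pc <- matrix(rep(cols - 0.5, each = length(rows)), length(rows), length(cols))
      vx <- c2 - c1
      vy <- r2 - r1
      tt <- ((pc - c1) * vx + (pr - r1) * vy) / max(vx^2 + vy^2, 1e-12)
      tt <- pmin(pmax(tt, 0), 1)
      d2 <- (pc - (c1 + tt * vx))^2 + (pr - (r1 + tt * vy))^2
      hit <- d2 <= r_px^2
      mask[rows, cols] <- mask[rows, cols] | hit
      # centerline raster
      bl <- bresenham(to_row(ed$y1[i]), to_col(ed$x1[i]),
                      to_row(ed$y2[i]), to_col(ed$x2[i]))
      skel[cbind(bl$r, bl$c)] <- TRUE
    }
  }
  # FAZ ellipse mask
  faz <- network$faz
  xr <- ((col(mask) - 0.5) * psz - faz$centre[1])
  yr <- ((row(mask) - 0.5) * psz - faz$centre[2])
  xe <- xr * cos(faz$rot) + yr * sin(faz$rot)
  ye <- -xr * sin(faz$rot) + yr * cos(faz$rot)
  faz_mask <- (xe / faz$a)^2 + (ye / faz$b)^2 < 1
  mask[faz_mask] <- FALSE
  skel[faz_mask] <- FALSE
  clean <- matrix(0, nr, nc)
  clean[mask] <- vessel_mean
  list(
    truth_mask = mask, truth_skeleton = skel, truth_faz_mask = faz_mask,
    clean_image = clean, vad_truth_pct = 100 * sum(mask) / length(mask)
  )
}

# Integer Bresenham line between (r1,c1) and (r2,c2).
bresenham <- function(r1, c1, r2, c2) {
  dr <- abs(r2 - r1)
  dc <- abs(c2 - c1)
  sr <- sign(r2 - r1)
  sc <- sign(c2 - c1)
  n <- max(dr, dc) + 1L
  rs <- integer(n)
  cs <- integer(n)
  err <- dc - dr
  r <- r1
  c <- c1
  for (i in seq_len(n)) {
    rs[i] <- r
    cs[i] <- c
    if (r == r2 && c == c2) {
      rs <- rs[seq_len(i)]
      cs <- cs[seq_len(i)]
      break
    }
    e2 <- 2L * err
    if (e2 > -dr) {
      err <- err - dr
      c <- c + sc
    }
    if (e2 < dc) {
      err <- err + dc
      r <- r + sr
    }
  }
  list(r = rs, c = cs)
}

#' Apply device noise to a clean image
#'
#' Adds folded-normal background noise everywhere and Gaussian speckle on
#' vessel pixels, then clips to the bit-depth range and rounds to the integer
#' intensity scale.  With both noise scales zero the clean image is returned
#' unchanged.  Deterministic under the model's seed.
#'
#' @param clean_image Numeric matrix, `vessel_mean` on vessel pixels, 0
#'   elsewhere (e.g. `rasterize_network()$clean_image` scaled by the model's
#'   vessel mean).
#' @param model An [noise_model()].
#' @param spec An [image_spec()] for the bit-depth range.
#' @return A numeric matrix on the integer intensity scale.
#' @export
apply_device_noise <- function(clean_image, model, spec = image_spec()) {
  stopifnot(inherits(model, "octa_noise_model"))
  if (model$background_sigma == 0 && model$speckle_cv == 0) {
    return(clean_image)
  }
  with_seed(model$seed, {
    n <- length(clean_image)
    z <- matrix(rnorm(n), nrow(clean_image))
    if (any(model$grain_px > 0)) {
      kv <- if (model$grain_px[1] > 0) gauss_kernels(model$grain_px[1])$g else 1
      kh <- if (model$grain_px[2] > 0) gauss_kernels(model$grain_px[2])$g else 1
      if (length(kv) > 1) z <- conv1d_vert(z, kv)
      if (length(kh) > 1) z <- conv1d_horiz(z, kh)
      z <- z / sqrt(sum(outer(kv, kh)^2))   # restore unit marginal variance
    }
    out <- clean_image + model$background_sigma * abs(z)
    ves <- clean_image > 0
    nv <- sum(ves)
    if (nv > 0 && model$speckle_cv > 0) {
      out[ves] <- out[ves] + rnorm(nv, 0, model$speckle_cv * model$vessel_mean)
    }
    matrix(round(pmin(pmax(out, 0), max_intensity(spec))), nrow(clean_image))
  })
}

#' Default network parameters for cohort simulation
#'
#' Density and geometry chosen to emulate a healthy macular plexus on a
#' 3 x 3 mm field: total vessel length around 170-210 mm, vessel diameters
#' near 19 um, FAZ area near 0.24 mm^2, with mild per-eye variation applied
#' by [generate_paired_cohort()].
#'
#' @param density Interior node intensity (points per mm^2).
#' @param faz_semi_axes Base FAZ semi-axes `c(a, b)` in mm.
#' @param edge_len_range Admissible edge lengths in mm.
#' @param diameter_lognorm `c(meanlog, sdlog)` of vessel diameter (mm).
#' @return A named list.
#' @export
cohort_network_params <- function(density = 140,
                                  faz_semi_axes = c(0.30, 0.25),
                                  edge_len_range = c(0.02, 0.13),
                                  diameter_lognorm = c(log(0.019), 0.18)) {
  list(
    density = density, faz_semi_axes = faz_semi_axes,
    edge_len_range = edge_len_range, diameter_lognorm = diameter_lognorm
  )
}

#' Generate a paired two-device phantom cohort
#'
#' Per eye, one shared ground-truth network is generated and imaged by both
#' device noise models (the paired, same-visit design).  Sub-seeds derive
#' deterministically from the cohort seed and the (participant, eye, device)
#' tuple, so regeneration is bit-identical and pairing is guaranteed.  FAZ
#' axes and rotation receive mild per-eye jitter (about 10%).
#'
#' @param n_participants Number of participants (>= 1), two eyes each by
#'   default.
#' @param model_a,model_b Noise models for device A and device B.
#' @param eyes_per_participant Eyes per participant, default 2.
#' @param spec An [image_spec()].
#' @param network_params From [cohort_network_params()].
#' @param seed Cohort-level seed.
#' @param device_labels `c(A, B)` labels attached to the images.
#' @param plexus Plexus label attached to all images.
#' @return A tibble with one row per (eye, device): identifiers, the
#'   `octa_image`, and shared truth list-columns (`truth_mask`,
#'   `truth_skeleton`, `truth_faz_mask`, `faz` parameters, `vad_truth_pct`).
#' @export
generate_paired_cohort <- function(n_participants = 25, model_a = device_preset("clean"),
                                   model_b = device_preset("noisy"),
                                   eyes_per_participant = 2, spec = image_spec(),
                                   network_params = cohort_network_params(),
                                   seed = 1L, device_labels = c("A", "B"),
                                   plexus = "SCP") {
  if (n_participants < 1) abort("`n_participants` must be >= 1.")
  rows <- list()
  for (p in seq_len(n_participants)) {
    for (e in seq_len(eyes_per_participant)) {
      net_seed <- derive_seed(seed, p, e, 0L)
      jit <- with_seed(derive_seed(seed, p, e, 9L), {
        c(runif(2, 0.9, 1.1), runif(1, 0, pi))
      })
      np <- network_params
      net <- generate_vessel_network(
        spec,
        density = np$density,
        faz_semi_axes = np$faz_semi_axes * jit[1:2],
        faz_rotation = jit[3],
        edge_len_range = np$edge_len_range,
        diameter_lognorm = np$diameter_lognorm,
        seed = net_seed
      )
      ras <- rasterize_network(net, spec, vessel_mean = 1)
      eye_id <- sprintf("E%d", e)
      part_id <- sprintf("P%02d", p)
      models <- list(model_a, model_b)
      for (d in 1:2) {
        mod <- models[[d]]
        mod$seed <- derive_seed(seed, p, e, d)
        img <- apply_device_noise(ras$clean_image * mod$vessel_mean, mod, spec)
        rows[[length(rows) + 1L]] <- tibble(
          participant = part_id, eye = eye_id, device = device_labels[d],
          plexus = plexus,
          image = list(en_face_image(img, spec, plexus, device_labels[d],
                                     part_id, eye_id)),
          truth_mask = list(ras$truth_mask),
          truth_skeleton = list(ras$truth_skeleton),
          truth_faz_mask = list(ras$truth_faz_mask),
          faz = list(net$faz),
          vad_truth_pct = ras$vad_truth_pct
        )
      }
    }
  }
  bind_rows(rows)
}
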