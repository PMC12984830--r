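# Binarization: windowed two-class fuzzy c-means thresholding of the
# vesselness map, and the composed enhance-then-threshold front end.

# Two-class fuzzy c-means (fuzzifier m = 2) on a histogram of window values.
# Returns the two class centres (sorted).  Degenerate (constant) windows
# return c(v, v).
fcm2_centres <- function(x, bins = 128L, tol = 1e-5, max_iter = 100L) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(c(rng[1], rng[1]))
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = bins)
  keep <- w > 0
  mids <- mids[keep]
  w <- w[keep]
  c1 <- rng[1]
  c2 <- rng[2]
  for (it in seq_len(max_iter)) {
    d1 <- (mids - c1)^2
    d2 <- (mids - c2)^2
    tot <- d1 + d2
    u1 <- ifelse(tot == 0, 0.5, d2 / tot)   # membership in class 1 (m = 2)
    u2 <- 1 - u1
    n1 <- c(crossprod(w * u1^2, mids)) / sum(w * u1^2)
    n2 <- c(crossprod(w * u2^2, mids)) / sum(w * u2^2)
    moved <- max(abs(n1 - c1), abs(n2 - c2))
    c1 <- n1
    c2 <- n2
    if (moved < tol) break
  }
  sort(c(c1, c2))
}

# 1-D linear interpolation matrix mapping values at grid positions `gpos`
# (increasing, covering [1, n]) to positions 1..n.
interp_matrix <- function(n, gpos) {
  g <- length(gpos)
  W <- matrix(0, n, g)
  seg <- findInterval(seq_len(n), gpos, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), g - 1L)
  lo <- gpos[seg]
  hi <- gpos[seg + 1L]
  frac <- (seq_len(n) - lo) / (hi - lo)
  W[cbind(seq_len(n), seg)] <- 1 - frac
  W[cbind(seq_len(n), seg + 1L)] <- frac
  W
}

#' Adaptive fuzzy-threshold binarization of a vesselness map
#'
#' Classifies each pixel as vessel or background by two-class fuzzy c-means
#' (fuzzifier 2): a pixel is vessel when its membership in the brighter class
#' exceeds 0.5, which for two classes reduces to exceeding the midpoint of the
#' two class centres.  Centres are estimated locally in `kernel_px`-sized
#' windows placed on a half-window grid and bilinearly interpolated between
#' window centres, approximating a full sliding window at tractable cost.
#'
#' Windows whose two centres are separated by less than `min_sep` (on the
#' normalized vesselness scale) carry no vessel/background contrast of their
#' own — for example a window wholly inside the avascular zone or deep inside
#' one structure — and inherit their class centres from the nearest
#' contrast-bearing windows through the interpolation.  When no window in the
#' whole image carries contrast (a constant map), every pixel falls to
#' background, the membership-tie rule.
#'
#' @param vmap An `octa_vesselness` (from [frangi_enhance()]) or a matrix.
#' @param kernel_px Window side length in pixels (>= 3); even values are
#'   incremented to the next odd number.
#' @param min_sep Minimum class-centre separation for a window to define a
#'   vessel class, default 0.05.
#' @return An object of class `octa_mask`: `mask` (logical matrix) and
#'   `provenance` (parameters used).
#' @export
fuzzy_threshold <- function(vmap, kernel_px = 70L, min_sep = 0.05) {
  v <- if (inherits(vmap, "octa_vesselness")) vmap$values else vmap
  if (!is.matrix(v)) abort("`vmap` must be an octa_vesselness or a matrix.")
  if (kernel_px < 3L) abort("`kernel_px` must be >= 3.")
  k <- as.integer(kernel_px)
  if (k %% 2L == 0L) k <- k + 1L
  nr <- nrow(v)
  nc <- ncol(v)
  half <- (k - 1L) %/% 2L
  stride <- max(1L, half)
  rc <- unique(c(seq(1L, nr, by = stride), nr))
  cc <- unique(c(seq(1L, nc, by = stride), nc))
  c1 <- matrix(NA_real_, length(rc), length(cc))
  c2 <- matrix(NA_real_, length(rc), length(cc))
  for (i in seq_along(rc)) {
    rs <- max(1L, rc[i] - half):min(nr, rc[i] + half)
    for (j in seq_along(cc)) {
      cs <- max(1L, cc[j] - half):min(nc, cc[j] + half)
      cen <- fcm2_centres(v[rs, cs])
      if (cen[2] - cen[1] >= min_sep) {
        c1[i, j] <- cen[1]
        c2[i, j] <- cen[2]
      }
    }
  }
  if (all(is.na(c1))) {
    # no window carries contrast: membership tie, everything background
    mask <- matrix(FALSE, nr, nc)
  } else {
    c1 <- fill_grid_na(c1)
    c2 <- fill_grid_na(c2)
    mid <- (c1 + c2) / 2
    tfull <- if (length(rc) == 1L && length(cc) == 1L) {
      matrix(mid[1, 1], nr, nc)
    } else if (length(rc) == 1L) {
      matrix(1, nr, 1) %*% (mid %*% t(interp_matrix(nc, cc)))
    } else if (length(cc) == 1L) {
      (interp_matrix(nr, rc) %*% mid) %*% matrix(1, 1, nc)
    } else {
      interp_matrix(nr, rc) %*% mid %*% t(interp_matrix(nc, cc))
    }
    mask <- v > tfull
  }
  structure(
    list(
      mask = mask,
      provenance = list(method = "fcm2", kernel_px = k, min_sep = min_sep)
    ),
    class = "octa_mask"
  )
}

# Replace NA grid cells by the mean of their non-NA 8-neighbours, iterating
# until the grid is full (low-contrast windows inherit centres from the
# nearest contrast-bearing windows).
fill_grid_na <- function(g) {
  while (anyNA(g)) {
    nas <- which(is.na(g), arr.ind = TRUE)
    filled <- FALSE
    for (k in seq_len(nrow(nas))) {
      r <- nas[k, 1]
      c <- nas[k, 2]
      nb <- g[max(1, r - 1):min(nrow(g), r + 1), max(1, c - 1):min(ncol(g), c + 1)]
      if (any(!is.na(nb))) {
        g[r, c] <- mean(nb, na.rm = TRUE)
        filled <- TRUE
      }
    }
    if (!filled) break
  }
  g
}

#' Default segmentation parameters
#'
#' The front-end settings applied identically to every image of an analysis
#' set: Frangi scales and blobness sensitivity, and the adaptive threshold
#' window.
#'
#' @param scales Frangi Gaussian scales (px).
#' @param beta Frangi blobness sensitivity.
#' @param kernel_px Fuzzy-threshold window side (px).
#' @param min_sep Minimum fuzzy class separation.
#' @return A named list of parameters.
#' @export
segmentation_config <- function(scales = c(1, 2, 3), beta = 0.5,
                                kernel_px = 70L, min_sep = 0.05) {
  list(scales = scales, beta = beta, kernel_px = kernel_px, min_sep = min_sep)
}

#' Enhance and binarize an en-face image
#'
#' Runs [frangi_enhance()] followed by [fuzzy_threshold()] with one set of
#' parameters, recording them as provenance.  This is the segmentation front
#' end applied with identical settings to every device being compared.
#'
#' @param image An [en_face_image()] or numeric matrix.
#' @param config Parameter list from [segmentation_config()].
#' @return An `octa_mask` whose provenance records all parameters.
#' @export
binarize_image <- function(image, config = segmentation_config()) {
  vmap <- frangi_enhance(image, scales = config$scales, beta = config$beta)
  out <- fuzzy_threshold(vmap, kernel_px = config$kernel_px, min_sep = config$min_sep)
  out$provenance <- c(out$provenance, list(
    frangi_scales = config$scales, frangi_beta = config$beta
  ))
  out
}
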