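# Vessel enhancement: 2-D Frangi vesselness over a small set of Gaussian
# scales, the front end of the segmentation pipeline.

# Replicate-padded separable convolution. `k` is an odd-length 1-D kernel.
conv1d_vert <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  nr <- nrow(m)
  m2 <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(nr, r), , drop = FALSE])
  out <- matrix(0, nr, ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * m2[(j - 1L) + seq_len(nr), , drop = FALSE]
  out
}

conv1d_horiz <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  nc <- ncol(m)
  m2 <- cbind(m[, rep(1L, r), drop = FALSE], m, m[, rep(nc, r), drop = FALSE])
  out <- matrix(0, nrow(m), nc)
  for (j in seq_along(k)) out <- out + k[j] * m2[, (j - 1L) + seq_len(nc), drop = FALSE]
  out
}

gauss_kernels <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- -t / sigma^2 * g
  g2 <- (t^2 - sigma^2) / sigma^4 * g
  # truncated derivative kernels must annihilate constants exactly
  g2 <- g2 - mean(g2)
  list(g = g, g1 = g1, g2 = g2)
}

# Scale-normalized Hessian of an image at Gaussian scale sigma.
hessian_at_scale <- function(m, sigma) {
  k <- gauss_kernels(sigma)
  s2 <- sigma^2
  list(
    xx = s2 * conv1d_vert(conv1d_horiz(m, k$g2), k$g),
    yy = s2 * conv1d_vert(conv1d_horiz(m, k$g), k$g2),
    xy = s2 * conv1d_vert(conv1d_horiz(m, k$g1), k$g1)
  )
}

#' Frangi vesselness enhancement
#'
#' Computes the classic 2-D Frangi vesselness for bright tubular structures on
#' a dark background, taking at each pixel the maximum response over a set of
#' Gaussian scales.  For eigenvalues `|l1| <= |l2|` of the scale-normalized
#' Hessian, the response is `exp(-Rb^2 / 2 beta^2) * (1 - exp(-S^2 / 2 gamma^2))`
#' with blobness `Rb = l1 / l2` and structureness `S = sqrt(l1^2 + l2^2)`,
#' and is zero wherever `l2 >= 0` (no bright ridge).  The map is normalized to
#' `[0, 1]` by its maximum when positive.
#'
#' Capillaries at ~5.9 um/px sampling span roughly 1-4 px, hence the default
#' scales `{1, 2, 3}` px.  `gamma` defaults to half the maximum structureness
#' at each scale (Frangi's heuristic).
#'
#' @param image An [en_face_image()], or a bare numeric matrix.
#' @param scales Gaussian scales in pixels, each >= 0.5.
#' @param beta Blobness sensitivity (dimensionless), default 0.5.
#' @param gamma Structureness sensitivity; `NULL` (default) uses half of the
#'   per-scale maximum structureness.
#' @return An object of class `octa_vesselness`: list with `values` (matrix in
#'   `[0,1]`) and `scales_used`.
#' @export
#' @examples
#' m <- matrix(0, 64, 64); m[30:33, ] <- 200  # a horizontal ridge
#' v <- frangi_enhance(m, scales = c(1, 2))
#' range(v$values)
frangi_enhance <- function(image, scales = c(1, 2, 3), beta = 0.5, gamma = NULL) {
  m <- if (inherits(image, "octa_image")) image$pixels else image
  if (!is.matrix(m)) abort("`image` must be an octa_image or a matrix.")
  if (length(scales) == 0L || any(scales < 0.5)) {
    abort("`scales` must be nonempty with every scale >= 0.5 px.")
  }
  best <- matrix(0, nrow(m), ncol(m))
  for (sg in scales) {
    h <- hessian_at_scale(m, sg)
    tmp <- sqrt(((h$xx - h$yy) / 2)^2 + h$xy^2)
    mid <- (h$xx + h$yy) / 2
    e1 <- mid + tmp
    e2 <- mid - tmp
    big <- abs(e1) >= abs(e2)      # l2 = eigenvalue of larger magnitude
    l2 <- ifelse(big, e1, e2)
    l1 <- ifelse(big, e2, e1)
    s2 <- l1^2 + l2^2
    g <- if (is.null(gamma)) sqrt(max(s2)) / 2 else gamma
    v <- matrix(0, nrow(m), ncol(m))
    # guard against numerically nonzero Hessians of flat images
    tol <- 1e-9 * max(1, max(abs(m)))
    ok <- l2 < -tol & g > tol
    if (any(ok)) {
      rb2 <- (l1[ok] / l2[ok])^2
      v[ok] <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2[ok] / (2 * g^2)))
    }
    best <- pmax(best, v)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  structure(list(values = best, scales_used = scales), class = "octa_vesselness")
}
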