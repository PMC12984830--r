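# Internal helpers shared across modules: matrix shifts, connected-component
# labelling, the percentile convention, and seed plumbing.

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

NEIGH8 <- cbind(
  dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dc = c(-1, 0, 1, -1, 1, -1, 0, 1)
)

# Count of set 8-neighbours for every pixel of a 0/1 matrix.
neighbour_count8 <- function(m) {
  out <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(nrow(NEIGH8))) {
    out <- out + shift_mat(m, NEIGH8[k, 1], NEIGH8[k, 2])
  }
  storage.mode(out) <- "integer"
  out
}

# Label connected components of a 0/1 matrix. 4-connectivity delegates to
# EBImage::bwlabel; 8-connectivity builds a pixel graph and uses igraph.
# Returns an integer matrix, 0 = background.
label_components <- function(mask, connectivity = 8L) {
  mode(mask) <- "integer"
  if (connectivity == 4L) {
    lab <- EBImage::bwlabel(mask)
    return(matrix(as.integer(lab), nrow(mask), ncol(mask)))
  }
  idx <- which(mask == 1L)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(out)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[idx] <- seq_along(idx)
  edges <- vector("list", 4L)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (k in seq_along(offs)) {
    nb <- shift_mat(id, offs[[k]][1], offs[[k]][2])
    sel <- which(mask == 1L & nb > 0L)
    if (length(sel)) edges[[k]] <- cbind(id[sel], nb[sel])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(e) && nrow(e)) g <- igraph::add_edges(g, t(e))
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

# Fill holes of a 0/1 mask (holes = background components not touching border).
fill_holes <- function(mask) {
  mode(mask) <- "integer"
  filled <- EBImage::fillHull(mask)
  matrix(as.integer(filled), nrow(mask), ncol(mask)) > 0L
}

# Percentile by linear interpolation between closest ranks, rank r = q (n - 1)
# on the sorted pool (0-based).  Used for the pooled noise threshold and all
# IQR reporting so the convention is uniform package-wide.
quantile_linear <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) abort("empty sample: percentile undefined.")
  if (n == 1L) return(rep(x, length(q)))
  r <- q * (n - 1)
  lo <- pmax(floor(r), 0)
  hi <- pmin(lo + 1, n - 1)
  frac <- r - lo
  x[lo + 1] * (1 - frac) + x[hi + 1] * frac
}

iqr_linear <- function(x) {
  qs <- quantile_linear(x, c(0.25, 0.75))
  qs[2] - qs[1]
}

# Deterministic sub-seed derivation: cohort seed plus a (participant, eye,
# stream) tuple, folded through a fixed multiplicative hash, kept < 2^31.
derive_seed <- function(seed, participant, eye, stream = 0L) {
  h <- (as.numeric(seed) %% 2147483647)
  for (k in c(participant * 2654435761, eye * 97531, stream * 7919)) {
    h <- (h * 31 + (k %% 2147483647)) %% 2147483647
  }
  as.integer(h %% 2147483562) + 1L
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
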