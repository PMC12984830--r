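# Shared fixtures, built in code.  The 50-eye paired cohort at full 512 px
# resolution is expensive (~6 min), so it is computed once per test session
# and reused by the acceptance and property tests.

.oq_cache <- new.env(parent = emptyenv())

oq_cohort_seed <- 20260930L

# Full-resolution paired cohort (25 participants x 2 eyes x 2 devices) under
# the shipped clean/noisy presets, plus its quantification.
oq_cohort <- function() {
  if (is.null(.oq_cache$cohort)) {
    .oq_cache$cohort <- generate_paired_cohort(
      n_participants = 25, seed = oq_cohort_seed
    )
  }
  .oq_cache$cohort
}

oq_cohort_metrics <- function() {
  if (is.null(.oq_cache$metrics)) {
    cfg <- run_config(seed = oq_cohort_seed)
    .oq_cache$metrics <- quantify_cohort(oq_cohort(), cfg)
  }
  .oq_cache$metrics
}

# One clean-preset 512 px eye with its ground truth, for segmentation tests.
oq_clean_eye <- function() {
  if (is.null(.oq_cache$eye)) {
    sp <- image_spec(512)
    net <- generate_vessel_network(sp, seed = 404L)
    ras <- rasterize_network(net, sp)
    mod <- device_preset("clean", seed = 405L)
    img <- apply_device_noise(ras$clean_image * mod$vessel_mean, mod, sp)
    .oq_cache$eye <- list(
      spec = sp, net = net, ras = ras,
      image = en_face_image(img, sp, "SCP", "A", "P1", "E1")
    )
  }
  .oq_cache$eye
}

# Draw a raster from pixel coordinates.
oq_raster <- function(nr, nc, rows, cols) {
  m <- matrix(FALSE, nr, nc)
  m[cbind(rows, cols)] <- TRUE
  m
}

# Brute-force 8-neighbour count oracle, the reference for branch/endpoint
# classification.
oq_neighbour_oracle <- function(sk) {
  nr <- nrow(sk)
  nc <- ncol(sk)
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!sk[r, c]) next
      cnt <- 0L
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr
          cc <- c + dc
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && sk[rr, cc]) {
            cnt <- cnt + 1L
          }
        }
      }
      out[r, c] <- cnt
    }
  }
  out
}
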