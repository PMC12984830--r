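# Phantom generator: determinism, FAZ exclusion, rasterization geometry and
# the folded-normal noise model.

test_that("network generation is deterministic and respects the FAZ ellipse", {
  sp <- image_spec(256)
  n1 <- generate_vessel_network(sp, density = 60, seed = 11)
  n2 <- generate_vessel_network(sp, density = 60, seed = 11)
  expect_identical(n1$edges, n2$edges)

  n3 <- generate_vessel_network(sp, density = 60, seed = 12)
  expect_false(identical(n1$edges, n3$edges))

  # exhaustive containment check over all polyline vertices
  faz <- n1$faz
  for (col in list(c("x1", "y1"), c("x2", "y2"))) {
    x <- n1$edges[[col[1]]] - faz$centre[1]
    y <- n1$edges[[col[2]]] - faz$centre[2]
    xr <- x * cos(faz$rot) + y * sin(faz$rot)
    yr <- -x * sin(faz$rot) + y * cos(faz$rot)
    expect_true(all((xr / faz$a)^2 + (yr / faz$b)^2 >= 1))
  }
  expect_true(all(n1$edges$radius_mm > 0))
  expect_true(all(n1$edges$x1 >= 0 & n1$edges$x1 <= sp$extent_mm))
})

test_that("zero density yields an empty, flagged network", {
  sp <- image_spec(128)
  expect_warning(net <- generate_vessel_network(sp, density = 0), "empty")
  expect_true(net$empty)
  expect_equal(nrow(net$edges), 0L)
  ras <- rasterize_network(net, sp)
  expect_equal(sum(ras$truth_mask), 0L)
  expect_equal(ras$vad_truth_pct, 0)
})

test_that("rasterization geometry matches closed forms", {
  # a single horizontal stroke: 3-px-wide ribbon of length ~100
  sp <- image_spec(256)
  psz <- sp$pixel_size_mm
  net <- generate_vessel_network(sp, density = 60, seed = 1)
  net$edges <- tibble::tibble(
    x1 = 50.5 * psz, y1 = 128.5 * psz, x2 = 150.5 * psz, y2 = 128.5 * psz,
    radius_mm = 1.5 * psz, rim = FALSE
  )
  net$empty <- FALSE
  # park the FAZ far away so it cannot clip the ribbon
  net$faz$centre <- c(0.35, 0.35)
  ras <- rasterize_network(net, sp)
  expect_lt(abs(sum(ras$truth_mask) - 300) / 300, 0.10)
  sk_cols <- range(which(colSums(ras$truth_skeleton) > 0))
  expect_equal(diff(sk_cols) + 1L, 101L)

  # FAZ ellipse area: pixel count vs pi a b
  net2 <- generate_vessel_network(image_spec(512),
    density = 60,
    faz_semi_axes = c(0.3, 0.25), seed = 2
  )
  ras2 <- rasterize_network(net2, image_spec(512))
  area <- sum(ras2$truth_faz_mask) * image_spec(512)$pixel_size_mm^2
  expect_lt(abs(area - pi * 0.3 * 0.25) / (pi * 0.3 * 0.25), 0.02)
})

test_that("device noise is reproducible and reduces to identity without noise", {
  sp <- image_spec(128)
  clean <- matrix(0, 128, 128)
  clean[40:50, ] <- 180
  id_model <- noise_model(0, 180, speckle_cv = 0, seed = 1)
  expect_identical(apply_device_noise(clean, id_model, sp), clean)

  m1 <- noise_model(20, 180, speckle_cv = 0.1, grain_px = 1.5, seed = 7)
  out1 <- apply_device_noise(clean, m1, sp)
  out2 <- apply_device_noise(clean, m1, sp)
  expect_identical(out1, out2)
  m2 <- noise_model(20, 180, speckle_cv = 0.1, grain_px = 1.5, seed = 8)
  expect_false(identical(out1, apply_device_noise(clean, m2, sp)))
})

test_that("background noise matches the folded-normal closed form", {
  # sd(|N(0, sigma)|) = sigma * sqrt(1 - 2/pi); vessel-free field, 16-bit to
  # avoid clipping
  sp <- image_spec(256, bit_depth = 16L)
  model <- noise_model(58, 100, speckle_cv = 0, seed = 3, bit_depth = 16L)
  img <- apply_device_noise(matrix(0, 256, 256), model, sp)
  expect_lt(abs(sd(img) - 58 * sqrt(1 - 2 / pi)) / (58 * sqrt(1 - 2 / pi)), 0.10)
  # grained speckle preserves the marginal distribution
  model_g <- noise_model(58, 100, speckle_cv = 0, grain_px = c(0.8, 2.5),
                         seed = 3, bit_depth = 16L)
  img_g <- apply_device_noise(matrix(0, 256, 256), model_g, sp)
  expect_lt(abs(sd(img_g) - 58 * sqrt(1 - 2 / pi)) / (58 * sqrt(1 - 2 / pi)), 0.10)
})

test_that("paired cohorts share truth per eye and have the right shape", {
  sp <- image_spec(96)
  coh <- generate_paired_cohort(
    n_participants = 2, spec = sp, seed = 5,
    network_params = cohort_network_params(density = 40)
  )
  expect_equal(nrow(coh), 2 * 2 * 2)  # participants x eyes x devices
  expect_setequal(unique(coh$device), c("A", "B"))
  # per-eye truth identical across devices; vessel and FAZ masks exclusive
  for (key in unique(paste(coh$participant, coh$eye))) {
    rows <- which(paste(coh$participant, coh$eye) == key)
    expect_identical(coh$truth_mask[[rows[1]]], coh$truth_mask[[rows[2]]])
    expect_equal(sum(coh$truth_mask[[rows[1]]] & coh$truth_faz_mask[[rows[1]]]), 0L)
  }
  # regeneration is bit-identical
  coh2 <- generate_paired_cohort(
    n_participants = 2, spec = sp, seed = 5,
    network_params = cohort_network_params(density = 40)
  )
  expect_identical(coh$image[[1]]$pixels, coh2$image[[1]]$pixels)
  # 25 participants x 2 eyes = 50 records per device (shape only, tiny grid;
  # empty-network warnings are the documented low-density behaviour)
  coh50 <- suppressWarnings(generate_paired_cohort(
    n_participants = 25, spec = image_spec(32), seed = 1,
    network_params = cohort_network_params(density = 5)
  ))
  expect_equal(nrow(coh50) / 2, 50)
})

test_that("identical models with the same sub-seed give identical paired images", {
  sp <- image_spec(96)
  ras <- rasterize_network(
    generate_vessel_network(sp, density = 40, seed = 9), sp
  )
  mod <- device_preset("clean", seed = 77)
  img_a <- apply_device_noise(ras$clean_image * mod$vessel_mean, mod, sp)
  img_b <- apply_device_noise(ras$clean_image * mod$vessel_mean, mod, sp)
  expect_identical(img_a, img_b)
  # all downstream paired differences are zero
  vad <- vapply(list(img_a, img_b), function(m) vessel_area_density(m > 0), 1)
  cd <- cliffs_delta(vad[1], vad[2])
  expect_equal(cd$delta, 0)
  wt <- wilcoxon_signed_rank(vad[1], vad[2])
  expect_equal(wt$p_value, 1)
  expect_true(wt$all_zero)
})

test_that("noise-floor SD increases with the background scale", {
  sp <- image_spec(256, bit_depth = 16L)
  sds <- vapply(c(5, 20, 60), function(sg) {
    model <- noise_model(sg, 100, speckle_cv = 0, grain_px = 1.5,
                         seed = 21, bit_depth = 16L)
    sd(apply_device_noise(matrix(0, 256, 256), model, sp))
  }, 1)
  expect_true(all(diff(sds) > 0))
})

test_that("truth VAD equals the mask pixel fraction exactly", {
  sp <- image_spec(192)
  ras <- rasterize_network(generate_vessel_network(sp, density = 80, seed = 2), sp)
  expect_identical(
    ras$vad_truth_pct,
    100 * sum(ras$truth_mask) / length(ras$truth_mask)
  )
  expect_identical(vessel_area_density(ras$truth_mask), ras$vad_truth_pct)
})
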