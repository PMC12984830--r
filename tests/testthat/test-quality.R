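# ROI geometry and the three image-quality formulas.

test_that("eroded rectangular FAZ matches Minkowski erosion", {
  m <- matrix(FALSE, 64, 64)
  m[21:40, 11:20] <- TRUE   # 20 x 10 rectangle
  roi <- eroded_faz_roi(m, erosion_px = 2)
  # brute-force per-pixel disk test oracle
  oracle <- matrix(FALSE, 64, 64)
  br <- EBImage::makeBrush(5, "disc")
  off <- which(br == 1, arr.ind = TRUE) - 3
  for (r in 1:64) for (c in 1:64) {
    rr <- r + off[, 1]
    cc <- c + off[, 2]
    if (all(rr >= 21 & rr <= 40 & cc >= 11 & cc <= 20)) oracle[r, c] <- TRUE
  }
  expect_identical(roi$mask, oracle)
  expect_equal(sum(roi$mask), 16 * 6)

  expect_identical(eroded_faz_roi(m, erosion_px = 0)$mask, m)
  tiny <- matrix(FALSE, 16, 16)
  tiny[7:9, 7:9] <- TRUE
  expect_error(eroded_faz_roi(tiny, erosion_px = 2), "erosion")
})

test_that("annulus ROI area matches the closed form", {
  sp <- image_spec(512)
  ctr <- c(256.5, 256.5)
  ring <- annulus_roi(ctr, sp, 0.5, 1.5)
  area <- sum(ring$mask) * sp$pixel_size_mm^2
  expect_lt(abs(area - pi * (1.5^2 - 0.5^2)) / (pi * 2), 0.01)
  expect_error(annulus_roi(ctr, sp, 1, 1))
  # corner-centred quarter annulus
  q <- annulus_roi(c(1, 1), sp, 0.2, 0.5)
  qarea <- sum(q$mask) * sp$pixel_size_mm^2
  expect_lt(abs(qarea - pi * (0.5^2 - 0.2^2) / 4) / (pi * (0.5^2 - 0.2^2) / 4), 0.03)
})

test_that("pooled threshold follows the closest-rank interpolation rule", {
  expect_equal(pooled_noise_threshold(1:40), 39.025)
  # rank r = 0.975 * 999 = 974.025 on the sorted pool 0..999
  expect_equal(pooled_noise_threshold(sample(0:999)), 974.025)
  expect_equal(pooled_noise_threshold(rep(3.5, 50)), 3.5)
  expect_warning(pooled_noise_threshold(1:10), "unstable")
  expect_error(pooled_noise_threshold(numeric()))
})

test_that("FAZ-noise rate counts strict exceedances", {
  img <- matrix(0, 40, 40)
  roi <- structure(list(mask = matrix(TRUE, 40, 40)[1:40, 1:40],
                        kind = "eroded_faz", geometry = list()),
                   class = "octa_roi")
  roi$mask <- matrix(FALSE, 40, 40)
  roi$mask[1:20, 1:20] <- TRUE               # 400-px ROI
  img[1:10, 1] <- 50                          # exactly 10 above threshold
  expect_equal(faz_noise_rate(img, roi, 10), 2.5)
  expect_equal(faz_noise_rate(img, roi, 50), 0)  # ties excluded
  expect_equal(faz_noise_rate(img, roi, 1e6), 0)
})

test_that("self-consistent pooling bounds the noise rate", {
  # one image whose own ROI defines the pool: rate <= 2.5% + 100/n
  set.seed(4)
  v <- matrix(abs(rnorm(2500, 0, 20)), 50, 50)
  roi <- structure(list(mask = matrix(TRUE, 50, 50), kind = "eroded_faz",
                        geometry = list()), class = "octa_roi")
  t_faz <- pooled_noise_threshold(as.vector(v))
  rate <- faz_noise_rate(v, roi, t_faz)
  expect_lte(rate, 2.5 + 100 / 2500)
})

test_that("CNR and noise-floor SD equal hand-computed values", {
  img <- matrix(0, 60, 60)
  ring <- structure(list(mask = matrix(FALSE, 60, 60), kind = "annulus",
                         geometry = list()), class = "octa_roi")
  faz <- ring
  faz$kind <- "eroded_faz"
  ring$mask[1:10, ] <- TRUE
  faz$mask[31:50, 1:20] <- TRUE               # 400 px
  img[ring$mask] <- 100
  img[faz$mask] <- rep(c(5, 15), 200)         # mean 10, sd 5.00626...
  s <- sd(img[faz$mask])
  expect_equal(contrast_to_noise(img, ring, faz), (100 - 10) / s)
  expect_equal(round(contrast_to_noise(img, ring, faz), 1), 18.0)
  img[faz$mask] <- 10
  expect_error(contrast_to_noise(img, ring, faz), "constant")
  img[faz$mask] <- rep(c(0, 10), 200)
  img[ring$mask] <- mean(img[faz$mask])
  expect_equal(contrast_to_noise(img, ring, faz), 0)

  expect_equal(noise_floor_sd(matrix(c(0, 10), 2, 1),
                              structure(list(mask = matrix(TRUE, 2, 1)),
                                        class = "octa_roi")), sqrt(50))
  expect_error(noise_floor_sd(matrix(5, 1, 1),
                              structure(list(mask = matrix(TRUE, 1, 1)),
                                        class = "octa_roi")))
})

test_that("CNR is invariant to intensity scaling and offset", {
  set.seed(6)
  img <- matrix(runif(64 * 64, 0, 200), 64, 64)
  ring <- structure(list(mask = matrix(FALSE, 64, 64)), class = "octa_roi")
  faz <- structure(list(mask = matrix(FALSE, 64, 64)), class = "octa_roi")
  ring$mask[1:10, ] <- TRUE
  faz$mask[40:60, 10:30] <- TRUE
  base <- contrast_to_noise(img, ring, faz)
  expect_equal(contrast_to_noise(img * 3.7, ring, faz), base)
  expect_equal(contrast_to_noise(img + 55, ring, faz), base)
})

test_that("a shared noise distribution calibrates the mean rate to 2.5%", {
  # 50 ROIs drawn from one folded-normal background; pooled threshold
  set.seed(77)
  rois <- replicate(50, abs(rnorm(2000, 0, 30)), simplify = FALSE)
  t_faz <- pooled_noise_threshold(unlist(rois))
  rates <- vapply(rois, function(v) 100 * mean(v > t_faz), 1)
  expect_lt(abs(mean(rates) - 2.5), 0.5)
})

test_that("noise-floor SD orders the device presets on every paired eye", {
  met <- oq_cohort_metrics()
  wide <- tidyr::pivot_wider(
    met[c("participant", "eye", "device", "noise_floor_sd")],
    names_from = "device", values_from = "noise_floor_sd"
  )
  ok <- stats::complete.cases(wide[c("A", "B")])
  expect_gte(sum(ok), 40)
  expect_true(all(wide$B[ok] > wide$A[ok]))
})

test_that("median CNR separates the presets by an order of magnitude", {
  met <- oq_cohort_metrics()
  med <- tapply(met$cnr, met$device, median, na.rm = TRUE)
  expect_gte(med[["A"]], 10 * med[["B"]])
})
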