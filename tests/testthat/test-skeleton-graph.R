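# Thinning, diameters, graph conversion and pruning.

test_that("a wide ribbon thins to a single one-pixel path", {
  m <- matrix(FALSE, 64, 128)
  m[31:33, 10:109] <- TRUE
  sk <- skeletonize(m)
  expect_true(all(sk$skeleton[!m] == FALSE))           # skeleton within mask
  expect_equal(max(colSums(sk$skeleton[, 12:107])), 1) # one pixel per column
  expect_true(all(which(rowSums(sk$skeleton) > 0) %in% 31:33))
  n <- sum(sk$skeleton)
  expect_gt(n, 90)
  expect_lt(n, 105)
  # no 2x2 fully-set block
  s <- sk$skeleton
  blk <- s[-nrow(s), -ncol(s)] & s[-1, -ncol(s)] & s[-nrow(s), -1] & s[-1, -1]
  expect_false(any(blk))
})

test_that("thinning is idempotent on 1-px lines and near-trivial on disks", {
  m <- matrix(FALSE, 32, 32)
  m[16, 5:28] <- TRUE
  expect_identical(skeletonize(m)$skeleton, m)
  # filled disk: medial locus is (near) a point, one component survives
  d <- matrix(FALSE, 41, 41)
  d[(row(d) - 21)^2 + (col(d) - 21)^2 <= 100] <- TRUE
  skd <- skeletonize(d)$skeleton
  expect_lte(sum(skd), 8)
  expect_gte(sum(skd), 1)
  lab <- octaquant:::label_components(matrix(as.integer(skd), 41, 41), 8L)
  expect_equal(max(lab), 1L)
})

test_that("distance-transform diameters recover ribbon and disk widths", {
  sp <- image_spec(512)
  m <- matrix(FALSE, 64, 128)
  m[30:34, 10:119] <- TRUE        # width 5
  sk <- skeletonize(m)
  dm <- diameter_map(m, sk, sp)
  med <- median(dm$px[sk$skeleton])
  expect_gte(med, 4)
  expect_lte(med, 6)
  expect_gte(med * sp$pixel_size_mm * 1000, 23.4)
  expect_lte(med * sp$pixel_size_mm * 1000, 35.2)

  d <- matrix(FALSE, 41, 41)
  d[(row(d) - 21)^2 + (col(d) - 21)^2 <= 100] <- TRUE
  skd <- matrix(FALSE, 41, 41)
  skd[21, 21] <- TRUE
  dmd <- diameter_map(d, skd, sp)
  expect_lt(abs(dmd$px[21, 21] - 20), 2.5)

  expect_equal(sp$pixel_size_mm * 1000, 5.859375)
  expect_error(diameter_map(matrix(FALSE, 4, 4),
                            matrix(TRUE, 4, 4), sp), "invariant")
})

test_that("graph conversion classifies the plus-sign and straight line", {
  sp <- image_spec(512)
  plus <- matrix(FALSE, 31, 31)
  plus[16, 6:26] <- TRUE
  plus[6:26, 16] <- TRUE
  g <- build_vessel_graph(plus, spec = sp)
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(nrow(g$endpoints), 4L)
  expect_equal(nrow(g$segments), 4L)

  line <- matrix(FALSE, 16, 128)
  line[8, 10:109] <- TRUE
  gl <- build_vessel_graph(line, spec = sp)
  expect_equal(nrow(gl$nodes), 0L)
  expect_equal(nrow(gl$endpoints), 2L)
  expect_equal(nrow(gl$segments), 1L)
  expect_equal(gl$segments$length_um, 99 * 5.859375)

  ge <- build_vessel_graph(matrix(FALSE, 8, 8), spec = sp)
  expect_equal(nrow(ge$segments), 0L)
  expect_equal(nrow(ge$nodes), 0L)
})

test_that("branch/endpoint classification matches the brute-force oracle", {
  # 512 seeded random 16 x 16 masks, exact agreement
  set.seed(99)
  for (i in 1:512) {
    sk <- matrix(runif(256) < 0.25, 16, 16)
    cnt_pkg <- octaquant:::neighbour_count8(matrix(as.integer(sk), 16, 16))
    cnt_orc <- oq_neighbour_oracle(sk)
    expect_identical(cnt_pkg[sk], cnt_orc[sk])
    if (any(sk)) {
      g <- build_vessel_graph(sk, spec = image_spec(512))
      branch_orc <- sum(sk & cnt_orc >= 3)
      expect_identical(sum(lengths(g$nodes$pixels)), branch_orc)
      expect_identical(nrow(g$endpoints), sum(sk & cnt_orc == 1))
    }
  }
})

test_that("graph reconstruction conserves skeleton pixels", {
  eye <- oq_clean_eye()
  sk <- skeletonize(binarize_image(eye$image))
  g <- build_vessel_graph(sk, spec = eye$spec)
  n_seg <- sum(vapply(g$segments$pixels, length, 1L))
  n_nod <- sum(vapply(g$nodes$pixels, length, 1L))
  expect_identical(n_seg + n_nod, sum(sk$skeleton))
})

test_that("pruning removes twigs and isolated specks, then dissolves joints", {
  sp <- image_spec(512)
  # Y-shape: two diagonal arms meeting at a single junction pixel, plus a
  # 1-px twig straight up from it
  y <- matrix(FALSE, 32, 32)
  for (k in 1:10) {
    y[16 + k, 16 - k] <- TRUE  # down-left arm
    y[16 + k, 16 + k] <- TRUE  # down-right arm
  }
  y[16, 16] <- TRUE            # junction
  y[15, 16] <- TRUE            # 1-px twig
  g <- build_vessel_graph(y, spec = sp)
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(nrow(g$segments), 3L)
  gp <- prune_graph(g, twig_px = 2)
  expect_equal(nrow(gp$nodes), 0L)
  expect_equal(nrow(gp$segments), 1L)
  expect_equal(gp$segments$length_px, 20 * sqrt(2))  # arm-to-arm path survives

  # all segments >= 2 px: pruning is a no-op
  plus <- matrix(FALSE, 31, 31)
  plus[16, 6:26] <- TRUE
  plus[6:26, 16] <- TRUE
  gpp <- prune_graph(build_vessel_graph(plus, spec = sp), twig_px = 2)
  expect_equal(nrow(gpp$segments), 4L)
  expect_equal(nrow(gpp$nodes), 1L)

  # two isolated 1-px specks are removed as noise
  sk <- matrix(FALSE, 16, 16)
  sk[3, 3] <- TRUE
  sk[12, 12] <- TRUE
  gs <- prune_graph(build_vessel_graph(sk, spec = sp), twig_px = 2)
  expect_equal(nrow(gs$segments), 0L)
})

test_that("pruning never increases node count or total length", {
  set.seed(123)
  for (i in 1:20) {
    sk <- skeletonize(matrix(runif(48 * 48) < 0.35, 48, 48))
    g <- build_vessel_graph(sk, spec = image_spec(512))
    gp <- prune_graph(g)
    expect_lte(nrow(gp$nodes), nrow(g$nodes))
    expect_lte(sum(gp$segments$length_px), sum(g$segments$length_px) + 1e-9)
  }
})
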