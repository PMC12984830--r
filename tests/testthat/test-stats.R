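# Normality gate, Wilcoxon signed-rank, Cliff's delta, comparison table.

test_that("the normality gate flags the obvious cases", {
  q <- qnorm(seq(0.025, 0.975, length.out = 20))
  g <- normality_gate(q)
  expect_gt(g$w, 0.99)
  expect_true(g$is_normal)
  gc <- normality_gate(rep(4, 10))
  expect_false(gc$is_normal)
  expect_true(gc$degenerate)
  gb <- normality_gate(c(rep(0, 10), rep(100, 10)))
  expect_lt(gb$p, 0.05)
  expect_error(normality_gate(c(1, 2)))
})

test_that("Wilcoxon exact path matches hand calculations and symmetry", {
  # n = 5, all differences positive -> two-sided p = 2/32
  w <- wilcoxon_signed_rank(6:10, 1:5)
  expect_equal(w$p_value, 0.0625)
  expect_equal(w$method, "exact")
  sym <- wilcoxon_signed_rank(c(1, -1), c(0, 0))
  expect_equal(sym$p_value, 1)
  allz <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(allz$p_value, 1)
  expect_true(allz$all_zero)
})

test_that("exact p equals full 2^n enumeration for n <= 10", {
  brute_p <- function(d) {
    rk <- rank(abs(d))
    n <- length(d)
    w_obs <- sum(rk[d > 0])
    grid <- expand.grid(rep(list(c(0, 1)), n))
    ws <- as.matrix(grid) %*% rk
    mu <- sum(rk) / 2
    min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  }
  set.seed(13)
  for (n in c(3, 5, 7, 10)) {
    for (rep in 1:5) {
      d <- round(rnorm(n, 0.4, 1), 1)
      d <- d[d != 0]
      if (length(d) < 3) next
      p_pkg <- wilcoxon_signed_rank(d, rep(0, length(d)))$p_value
      expect_equal(p_pkg, brute_p(d), tolerance = 1e-12)
    }
  }
})

test_that("large-sample path agrees with the reference implementation", {
  set.seed(50)
  a <- rnorm(50, 0.3)
  b <- rnorm(50)
  p_pkg <- wilcoxon_signed_rank(a, b)$p_value
  p_ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-6)
  # exact path vs R's exact distribution (tie-free)
  set.seed(51)
  a2 <- rnorm(18, 0.5)
  b2 <- rnorm(18)
  p_pkg2 <- wilcoxon_signed_rank(a2, b2)$p_value
  p_ref2 <- wilcox.test(a2, b2, paired = TRUE, exact = TRUE)$p.value
  expect_equal(p_pkg2, p_ref2, tolerance = 1e-10)
})

test_that("Cliff's delta follows its defining formula", {
  all_up <- cliffs_delta(2:51, 1:50)
  expect_equal(all_up$delta, 1)
  mixed <- cliffs_delta(c(2, 3, 4, 1), c(1, 2, 4, 2))
  expect_equal(mixed$delta, 0.25)
  expect_equal(mixed$n_plus, 2L)
  expect_equal(mixed$n_minus, 1L)
  expect_equal(mixed$n_ties, 1L)
  ties <- cliffs_delta(rep(3, 7), rep(3, 7))
  expect_equal(ties$delta, 0)
})

test_that("delta is antisymmetric and bounded", {
  set.seed(21)
  for (i in 1:25) {
    a <- sample(1:10, 12, replace = TRUE)
    b <- sample(1:10, 12, replace = TRUE)
    d1 <- cliffs_delta(a, b)$delta
    d2 <- cliffs_delta(b, a)$delta
    expect_equal(d1, -d2)
    expect_lte(abs(d1), 1)
    cd <- cliffs_delta(a, b)
    if (abs(d1) == 1) expect_equal(cd$n_ties, 0L)
  }
})

test_that("comparison tables handle the null cohort and match sort oracles", {
  set.seed(33)
  base <- tibble::tibble(
    participant = rep(sprintf("P%02d", 1:10), each = 2),
    eye = rep(c("E1", "E2"), 10),
    plexus = "SCP",
    vad_pct = runif(20, 30, 50),
    mvl_um = runif(20, 30, 50)
  )
  null_cohort <- dplyr::bind_rows(
    dplyr::mutate(base, device = "A"),
    dplyr::mutate(base, device = "B")
  )
  cmp <- compare_devices(null_cohort, reference = "A",
                         metrics = c("vad_pct", "mvl_um"))
  expect_true(all(cmp$delta == 0))
  expect_true(all(cmp$p_value == 1))

  shifted <- dplyr::bind_rows(
    dplyr::mutate(base, device = "A"),
    dplyr::mutate(base, device = "B",
                  vad_pct = .data$vad_pct + runif(20, 0.5, 3))
  )
  cmp2 <- compare_devices(shifted, reference = "A", metrics = "vad_pct")
  expect_equal(cmp2$delta, -1)
  # IQR equals 75th - 25th percentile from an independent sort oracle
  v <- base$vad_pct
  s <- sort(v)
  r <- 0.75 * (length(v) - 1)
  q75 <- s[floor(r) + 1] * (1 - (r - floor(r))) + s[floor(r) + 2] * (r - floor(r))
  r <- 0.25 * (length(v) - 1)
  q25 <- s[floor(r) + 1] * (1 - (r - floor(r))) + s[floor(r) + 2] * (r - floor(r))
  expect_equal(cmp2$iqr_ref, q75 - q25)
  # summary invariance under pair reordering
  perm <- sample(nrow(shifted))
  cmp3 <- compare_devices(shifted[perm, ], reference = "A", metrics = "vad_pct")
  expect_equal(cmp3$median_ref, cmp2$median_ref)
  expect_equal(cmp3$iqr_ref, cmp2$iqr_ref)
  expect_equal(cmp3$delta, cmp2$delta)
  expect_equal(cmp3$p_value, cmp2$p_value)
})

test_that("tidy, glance and autoplot work on comparison tables", {
  base <- tibble::tibble(
    participant = rep(sprintf("P%02d", 1:8), each = 2),
    eye = rep(c("E1", "E2"), 8), plexus = "SCP",
    fd = rnorm(16, 1.98, 0.002), vad_pct = runif(16, 30, 50)
  )
  coh <- dplyr::bind_rows(
    dplyr::mutate(base, device = "A"),
    dplyr::mutate(base, device = "B", vad_pct = .data$vad_pct + 1)
  )
  cmp <- compare_devices(coh, reference = "A")
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("metric", "delta", "p_value") %in% names(td)))
  gl <- glance(cmp)
  expect_equal(gl$n_metrics, nrow(cmp))
  p <- ggplot2::autoplot(cmp)
  expect_s3_class(p, "ggplot")
})
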