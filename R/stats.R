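# Paired two-device statistics: Shapiro-Wilk normality gate, Wilcoxon
# signed-rank with the classical zero-drop / mid-rank conventions, Cliff's
# delta, and the comparison-table builder.

#' Shapiro-Wilk normality gate
#'
#' Tests a metric's distribution for normality.  The result only selects the
#' summary display (mean/SD when normal, median/IQR otherwise); the paired
#' test is always the Wilcoxon signed-rank regardless of the gate.  Constant
#' samples, for which W is undefined, are flagged non-normal.
#'
#' @param values Numeric sample, 3 to 5000 observations.
#' @param alpha Significance level of the gate, default 0.05.
#' @return A list with `is_normal`, `p`, `w`, and `degenerate`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) abort("Shapiro-Wilk requires at least 3 observations.")
  if (n > 5000L) abort("Shapiro-Wilk is defined here for at most 5000 observations.")
  if (diff(range(values)) == 0) {
    return(list(is_normal = FALSE, p = NA_real_, w = NA_real_, degenerate = TRUE))
  }
  sw <- shapiro.test(values)
  list(
    is_normal = sw$p.value >= alpha, p = sw$p.value,
    w = unname(sw$statistic), degenerate = FALSE
  )
}

# Exact null distribution of the signed-rank sum with mid-ranks: the
# generating function prod_i (1 + x^(2 r_i)) is expanded by convolution
# (doubling keeps tied mid-ranks integral).  Identical to enumerating all 2^n
# sign assignments, but feasible at n = 25.
signed_rank_exact_p <- function(ranks, w_plus) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  poly <- numeric(total + 1L)
  poly[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), poly[seq_len(total + 1L - r)])
    poly <- poly + shifted
  }
  probs <- poly / 2^length(ranks)
  w2 <- round(2 * w_plus)
  mu <- total / 2
  # two-sided: double the smaller tail, capped at 1
  lo <- sum(probs[seq_len(w2 + 1L)])                      # P(W <= w)
  hi <- sum(probs[(w2 + 1L):(total + 1L)])                # P(W >= w)
  min(1, 2 * min(lo, hi))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of paired differences with the classical
#' conventions: zero differences are dropped, tied absolute differences
#' receive mid-ranks, the null distribution is computed exactly for n <= 25
#' (by expanding the signed-rank generating function, equivalent to full
#' enumeration of sign assignments) and by normal approximation with
#' continuity and tie corrections above.
#'
#' @param a,b Paired numeric vectors, or `a` a data frame with columns
#'   `value_a`, `value_b`.
#' @param exact_n Largest n for the exact path, default 25.
#' @return A list with `p_value`, `statistic` (W+), `n_used`, `n_zero`,
#'   `method`, and `all_zero`.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, exact_n = 25L) {
  if (is.data.frame(a)) {
    b <- a$value_b
    a <- a$value_a
  }
  if (length(a) != length(b)) abort("paired vectors must have equal length.")
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  if (length(d) < 1L) abort("need at least one pair.")
  nz <- d != 0
  n0 <- sum(!nz)
  d <- d[nz]
  n <- length(d)
  if (n == 0L) {
    return(list(
      p_value = 1, statistic = 0, n_used = 0L, n_zero = n0,
      method = "degenerate", all_zero = TRUE
    ))
  }
  rk <- rank(abs(d))               # mid-ranks for ties
  w_plus <- sum(rk[d > 0])
  if (n <= exact_n) {
    p <- signed_rank_exact_p(rk, w_plus)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(
    p_value = p, statistic = w_plus, n_used = n, n_zero = n0,
    method = method, all_zero = FALSE
  )
}

#' Cliff's delta for paired data
#'
#' `delta = (n_plus - n_minus) / n`, where `n_plus` and `n_minus` count pairs
#' in which the reference series exceeds (respectively falls below) the
#' comparator, and `n` is the total number of pairs; ties contribute to `n`
#' only.  `delta = 1` means the reference dominated every pair.
#'
#' @inheritParams wilcoxon_signed_rank
#' @return A list with `delta`, `n_plus`, `n_minus`, `n_ties`, `n`.
#' @export
#' @examples
#' cliffs_delta(c(2, 3, 4, 1), c(1, 2, 4, 2))  # (2 - 1) / 4 = 0.25
cliffs_delta <- function(a, b = NULL) {
  if (is.data.frame(a)) {
    b <- a$value_b
    a <- a$value_a
  }
  if (length(a) != length(b)) abort("paired vectors must have equal length.")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 1L) abort("need at least one pair.")
  n_plus <- sum(a > b)
  n_minus <- sum(a < b)
  list(
    delta = (n_plus - n_minus) / n,
    n_plus = n_plus, n_minus = n_minus, n_ties = n - n_plus - n_minus, n = n
  )
}

#' Paired device-comparison table
#'
#' Builds one comparison row per metric (and plexus) from a long metrics
#' table: summaries for each device (median/IQR by default, mean/SD when the
#' normality gate passes or the metric is listed in `mean_sd_metrics`), the
#' two-sided Wilcoxon signed-rank p-value, and Cliff's delta with the
#' reference device's value as the first series.  Eyes missing either device
#' are excluded from that metric's row (with a count kept); p-values are
#' reported unadjusted.
#'
#' @param records Tibble with columns `participant`, `eye`, `device`,
#'   `plexus`, and one column per metric.
#' @param reference Device label used as the reference (first) series.
#' @param metrics Character vector of metric columns to compare; defaults to
#'   all numeric columns except identifiers.
#' @param mean_sd_metrics Metrics always summarized as mean (SD); fractal
#'   dimension by convention.
#' @return A tibble of class `octa_comparison`, one row per plexus x metric.
#' @export
compare_devices <- function(records, reference,
                            metrics = NULL, mean_sd_metrics = "fd") {
  stopifnot(is.data.frame(records))
  need <- c("participant", "eye", "device", "plexus")
  if (!all(need %in% names(records))) {
    abort("`records` must have participant, eye, device and plexus columns.")
  }
  devs <- unique(records$device)
  if (length(devs) != 2L) {
    if (length(devs) < 2L) {
      warn("only one device present: comparison table is empty.")
      out <- tibble(
        plexus = character(), metric = character(), n = integer(),
        summary_ref = character(), summary_other = character(),
        median_ref = numeric(), iqr_ref = numeric(),
        median_other = numeric(), iqr_other = numeric(),
        normal_ref = logical(), normal_other = logical(),
        p_value = numeric(), delta = numeric(),
        n_plus = integer(), n_minus = integer(), n_ties = integer(),
        reference = character(), other = character()
      )
      class(out) <- c("octa_comparison", class(out))
      return(out)
    }
    abort("more than two devices present; compare two at a time.")
  }
  if (!reference %in% devs) abort(sprintf("reference device '%s' not in data.", reference))
  other <- setdiff(devs, reference)
  if (is.null(metrics)) {
    metrics <- names(records)[vapply(records, is.numeric, TRUE)]
    metrics <- setdiff(metrics, c("participant", "eye", "seed", "t_faz_used"))
  }
  rows <- list()
  for (plx in unique(records$plexus)) {
    sub <- records[records$plexus == plx, , drop = FALSE]
    wide_ref <- sub[sub$device == reference, c("participant", "eye", metrics)]
    wide_oth <- sub[sub$device == other, c("participant", "eye", metrics)]
    paired <- inner_join(wide_ref, wide_oth,
      by = c("participant", "eye"), suffix = c("_ref", "_oth")
    )
    for (mt in metrics) {
      va <- paired[[paste0(mt, "_ref")]]
      vb <- paired[[paste0(mt, "_oth")]]
      ok <- is.finite(va) & is.finite(vb)
      va <- va[ok]
      vb <- vb[ok]
      if (length(va) < 1L) next
      gate_a <- if (length(va) >= 3L) normality_gate(va) else
        list(is_normal = FALSE)
      gate_b <- if (length(vb) >= 3L) normality_gate(vb) else
        list(is_normal = FALSE)
      use_mean <- mt %in% mean_sd_metrics ||
        (isTRUE(gate_a$is_normal) && isTRUE(gate_b$is_normal))
      fmt <- function(v) {
        if (use_mean) {
          sprintf("%.4g (%.3g)", mean(v), sd(v))
        } else {
          sprintf("%.4g (%.3g)", quantile_linear(v, 0.5), iqr_linear(v))
        }
      }
      wt <- wilcoxon_signed_rank(va, vb)
      cd <- cliffs_delta(va, vb)
      rows[[length(rows) + 1L]] <- tibble(
        plexus = plx, metric = mt, n = length(va),
        summary_ref = fmt(va), summary_other = fmt(vb),
        median_ref = quantile_linear(va, 0.5), iqr_ref = iqr_linear(va),
        median_other = quantile_linear(vb, 0.5), iqr_other = iqr_linear(vb),
        normal_ref = isTRUE(gate_a$is_normal), normal_other = isTRUE(gate_b$is_normal),
        p_value = wt$p_value, delta = cd$delta,
        n_plus = cd$n_plus, n_minus = cd$n_minus, n_ties = cd$n_ties,
        reference = reference, other = other
      )
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("octa_comparison", class(out))
  out
}
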