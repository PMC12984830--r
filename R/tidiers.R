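# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a device-comparison table
#'
#' Returns the comparison as a plain tibble with one row per plexus x metric
#' and the key inferential columns first.
#'
#' @param x An `octa_comparison` from [compare_devices()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy octa_comparison
#' @export
tidy.octa_comparison <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "octa_comparison")
  select(
    out, "plexus", "metric", "n", "delta", "p_value",
    "n_plus", "n_minus", "n_ties",
    "median_ref", "iqr_ref", "median_other", "iqr_other",
    "summary_ref", "summary_other", "reference", "other"
  )
}

#' Glance at a device-comparison table
#'
#' @param x An `octa_comparison`.
#' @param alpha Significance level used to count significant metrics.
#' @param ... Unused.
#' @return A one-row tibble: number of metrics, number significant, number
#'   with |delta| = 1 (complete dominance), and the device labels.
#' @method glance octa_comparison
#' @export
glance.octa_comparison <- function(x, alpha = 0.05, ...) {
  tibble(
    n_metrics = nrow(x),
    n_significant = sum(x$p_value < alpha, na.rm = TRUE),
    n_dominant = sum(abs(x$delta) == 1, na.rm = TRUE),
    reference = if (nrow(x)) x$reference[[1]] else NA_character_,
    other = if (nrow(x)) x$other[[1]] else NA_character_
  )
}

#' Plot a device-comparison table
#'
#' Dot plot of Cliff's delta per metric (faceted by plexus when several are
#' present), annotated with the Wilcoxon p-value; the dashed lines mark the
#' complete-dominance endpoints at +/-1.
#'
#' @param object An `octa_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot octa_comparison
#' @export
autoplot.octa_comparison <- function(object, ...) {
  df <- tidy(object)
  df$sig <- df$p_value < 0.05
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$metric)) +
    ggplot2::geom_vline(xintercept = c(-1, 0, 1), linetype = c(2, 1, 2),
                        colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sig), size = 3) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#b2182b", `FALSE` = "grey40"),
      name = "p < 0.05"
    ) +
    ggplot2::xlim(-1.05, 1.05) +
    ggplot2::labs(
      x = sprintf("Cliff's delta (%s vs %s)",
                  df$reference[1] %||% "ref", df$other[1] %||% "other"),
      y = NULL
    ) +
    ggplot2::theme_minimal()
  if (length(unique(df$plexus)) > 1L) {
    p <- p + ggplot2::facet_wrap(~plexus)
  }
  p
}

#' Plot an en-face image
#'
#' Grayscale raster of the intensity grid in physical coordinates.
#'
#' @param object An `octa_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot octa_image
#' @export
autoplot.octa_image <- function(object, ...) {
  px <- object$spec$pixel_size_mm
  df <- tibble(
    x = (as.vector(col(object$pixels)) - 0.5) * px,
    y = (as.vector(row(object$pixels)) - 0.5) * px,
    intensity = as.vector(object$pixels)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("%s %s", object$device, object$plexus)) +
    ggplot2::theme_minimal()
}

#' Export a vessel graph as an edge-list table
#'
#' One row per segment with end-node ids, pixel count, length and mean
#' diameter; suitable for writing to CSV.
#'
#' @param x An `octa_graph`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy octa_graph
#' @export
tidy.octa_graph <- function(x, ...) {
  select(
    x$segments, "segment", "node_a", "node_b", "n_pixels",
    "length_um", "mean_diameter_um", "cycle"
  )
}
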