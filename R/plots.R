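#' Rose plot of a direction histogram
#'
#' Draws the angular histogram as radial bars over the half-disc
#' [0, 180] degrees, with 0 (purely medial movement) pointing right and
#' 180 (purely lateral) pointing left; bar length is the cell count in
#' each bin.
#'
#' @param x a [direction_histogram()].
#' @param col bar fill colour.
#' @param main plot title.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.direction_histogram <- function(x, col = "grey40", main = NULL, ...) {
  counts <- x$counts
  edges <- x$bin_edges * pi / 180
  r_max <- max(counts, 1)
  if (is.null(main)) {
    main <- if (!is.null(x$group)) paste("Net direction:", x$group)
    else "Net direction"
  }
  op <- graphics::par(mar = c(1, 1, 3, 1))
  on.exit(graphics::par(op))
  plot(NA, xlim = c(-r_max, r_max) * 1.1, ylim = c(-r_max * 0.15, r_max * 1.1),
       asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    th <- seq(edges[i], edges[i + 1L], length.out = 20L)
    graphics::polygon(c(0, counts[i] * cos(th)), c(0, counts[i] * sin(th)),
                      col = col, border = "white")
  }
  th <- seq(0, pi, length.out = 100L)
  graphics::lines(r_max * cos(th), r_max * sin(th), col = "grey70")
  graphics::segments(-r_max, 0, r_max, 0, col = "grey70")
  graphics::text(r_max * 1.08, 0, "0° (medial)", adj = 0, cex = 0.8)
  graphics::text(-r_max * 1.08, 0, "180° (lateral)", adj = 1, cex = 0.8)
  graphics::text(0, r_max * 1.07, "90°", cex = 0.8)
  invisible(x)
}

#' Dot plot of a per-cell or per-embryo metric by group
#'
#' One jittered point per observation, with a horizontal group-mean bar:
#' the standard presentation for small-cohort kinematic metrics.
#'
#' @param values numeric vector of metric values.
#' @param group factor/character of the same length.
#' @param ylab y-axis label (metric name and units).
#' @param main plot title.
#' @return Invisibly, the per-group means.
#' @export
plot_metric_dots <- function(values, group, ylab = "", main = "") {
  group <- factor(group)
  keep <- !is.na(values)
  values <- values[keep]
  group <- droplevels(group[keep])
  graphics::stripchart(values ~ group, vertical = TRUE, method = "jitter",
                       pch = 16, col = "grey40", ylab = ylab, main = main)
  means <- tapply(values, group, mean)
  for (i in seq_along(means)) {
    graphics::segments(i - 0.2, means[i], i + 0.2, means[i], lwd = 2,
                       col = "red3")
  }
  invisible(means)
}

#' Divergence plot of a gap time course
#'
#' Group-mean representative gap per stage with standard-error bars;
#' stages where the two groups differ at p < 0.05 are starred.
#'
#' @param x a [gap_timecourse()] result.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.gap_timecourse <- function(x, ...) {
  groups <- attr(x, "groups")
  n <- nrow(x)
  xs <- seq_len(n)
  ylim <- range(c(x$mean_a - x$se_a, x$mean_a + x$se_a,
                  x$mean_b - x$se_b, x$mean_b + x$se_b))
  plot(xs, x$mean_a, type = "b", pch = 16, ylim = ylim, xaxt = "n",
       xlab = "stage", ylab = "representative gap (µm)",
       main = "Bilateral domain gap over development")
  graphics::axis(1, at = xs, labels = x$stage_label)
  graphics::arrows(xs, x$mean_a - x$se_a, xs, x$mean_a + x$se_a,
                   angle = 90, code = 3, length = 0.03)
  graphics::lines(xs, x$mean_b, type = "b", pch = 17, col = "red3")
  graphics::arrows(xs, x$mean_b - x$se_b, xs, x$mean_b + x$se_b,
                   angle = 90, code = 3, length = 0.03, col = "red3")
  sig <- x$p_value < 0.05
  if (any(sig)) {
    graphics::text(xs[sig], pmax(x$mean_a, x$mean_b)[sig] +
                     0.05 * diff(ylim), "*", cex = 1.4)
  }
  graphics::legend("topright", legend = groups, pch = c(16, 17),
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}
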