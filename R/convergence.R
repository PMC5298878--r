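#' Bilateral-domain gap statistic
#'
#' Measures the distance between the medial edges of the left and right
#' bilateral domains at `n_points` anterior-posterior positions spaced
#' `spacing` micrometres apart (three points 200 um apart by default) and
#' takes the largest as the embryo's representative gap. Edge x
#' positions at the sample points are linearly interpolated between the
#' supplied edge samples.
#'
#' @param edges a `domain_edges` table restricted to one embryo and
#'   stage (see [read_domain_edges()]), or a larger table together with
#'   `embryo_id` and `stage_label` to select.
#' @param anchor where the sample points sit along the AP axis:
#'   `"centered"` on the midpoint of the edges' common y span, or
#'   `"anterior"` (topmost point at the anterior end of the span).
#' @param spacing distance between consecutive sample points, um.
#' @param n_points number of sample points.
#' @param embryo_id,stage_label optional selectors into a multi-embryo
#'   table.
#' @return A `gap_measurement` list: `embryo_id`, `stage_label`,
#'   `sample_points` (y positions), `distances`, and
#'   `representative_gap = max(distances)`.
#' @export
measure_gap <- function(edges, anchor = c("centered", "anterior"),
                        spacing = 200, n_points = 3L,
                        embryo_id = NULL, stage_label = NULL) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(edges, "domain_edges") || is.data.frame(edges))
  if (!is.null(embryo_id)) edges <- edges[edges$embryo_id == embryo_id, ]
  if (!is.null(stage_label)) {
    edges <- edges[edges$stage_label == stage_label, ]
  }
  eid <- unique(edges$embryo_id)
  stg <- unique(edges$stage_label)
  if (length(eid) != 1L || length(stg) != 1L) {
    stop("measure_gap needs edges for exactly one (embryo, stage); ",
         "use embryo_id/stage_label to select", call. = FALSE)
  }
  left <- edges[edges$side == "left", ]
  right <- edges[edges$side == "right", ]
  if (nrow(left) < 2L || nrow(right) < 2L) {
    stop(sprintf("embryo '%s': both edges need >= 2 samples", eid),
         call. = FALSE)
  }
  span <- c(max(min(left$y), min(right$y)), min(max(left$y), max(right$y)))
  ys <- switch(anchor,
               centered = mean(span) + (seq_len(n_points) - (n_points + 1) / 2) *
                 spacing,
               anterior = span[2L] - (n_points - seq_len(n_points)) * spacing)
  ys <- sort(ys)
  if (min(ys) < span[1L] - 1e-9 || max(ys) > span[2L] + 1e-9) {
    stop(sprintf(
      "embryo '%s': edges span only %.0f um in y; cannot place %d points %.0f um apart",
      eid, diff(span), n_points, spacing), call. = FALSE)
  }
  interp <- function(curve, y) {
    stats::approx(curve$y, curve$x, xout = y, ties = "ordered")$y
  }
  d <- interp(right, ys) - interp(left, ys)
  if (any(d < -1e-9)) {
    stop(sprintf("embryo '%s': right edge left of left edge at a sample point",
                 eid), call. = FALSE)
  }
  d <- pmax(d, 0)
  structure(list(embryo_id = eid, stage_label = stg, sample_points = ys,
                 distances = d, representative_gap = max(d)),
            class = "gap_measurement")
}

#' @export
print.gap_measurement <- function(x, ...) {
  cat(sprintf("<gap_measurement> embryo '%s', stage '%s'\n", x$embryo_id,
              x$stage_label))
  cat(sprintf("  y = %s um -> gap = %s um\n",
              paste(signif(x$sample_points, 4L), collapse = ", "),
              paste(signif(x$distances, 4L), collapse = ", ")))
  cat(sprintf("  representative gap (max): %.4g um\n", x$representative_gap))
  invisible(x)
}

#' Gap measurements for every embryo and stage in an edge table
#'
#' @param edges a multi-embryo `domain_edges` table; an optional `group`
#'   column is carried through.
#' @inheritParams measure_gap
#' @return Data frame with one row per (embryo, stage):
#'   `embryo_id`, `group`, `stage_label`, `representative_gap`.
#' @export
measure_gaps <- function(edges, anchor = c("centered", "anterior"),
                         spacing = 200, n_points = 3L) {
  anchor <- match.arg(anchor)
  keys <- unique(edges[, c("embryo_id", "stage_label"), drop = FALSE])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- edges[edges$embryo_id == keys$embryo_id[i] &
                   edges$stage_label == keys$stage_label[i], ]
    g <- measure_gap(sub, anchor = anchor, spacing = spacing,
                     n_points = n_points)
    data.frame(embryo_id = g$embryo_id,
               group = if (!is.null(sub$group)) sub$group[1L] else NA_character_,
               stage_label = g$stage_label,
               representative_gap = g$representative_gap,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Per-stage group comparison of representative gaps
#'
#' Compares the representative gaps of two cohorts at each developmental
#' stage with the unpaired two-tailed Student's t-test, tracing when the
#' bilateral domains of the two groups begin to diverge. Stages with
#' fewer than 2 embryos in either group are skipped with a warning.
#'
#' @param measurements data frame from [measure_gaps()] with a `group`
#'   column containing exactly two levels.
#' @param groups optional character length-2 giving the (reference,
#'   comparison) group order; defaults to sorted unique values.
#' @return A `gap_timecourse` data frame: per stage, group means, SEs,
#'   ns, `t_statistic`, `p_value`.
#' @export
gap_timecourse <- function(measurements, groups = NULL) {
  stopifnot(is.data.frame(measurements),
            all(c("group", "stage_label", "representative_gap") %in%
                  names(measurements)))
  if (is.null(groups)) groups <- sort(unique(measurements$group))
  if (length(groups) != 2L) {
    stop("gap_timecourse needs exactly two groups", call. = FALSE)
  }
  stages <- unique(measurements$stage_label)
  rows <- list()
  for (st in stages) {
    a <- measurements$representative_gap[measurements$stage_label == st &
                                           measurements$group == groups[1L]]
    b <- measurements$representative_gap[measurements$stage_label == st &
                                           measurements$group == groups[2L]]
    if (length(a) < 2L || length(b) < 2L) {
      warning(sprintf(
        "stage '%s' skipped: fewer than 2 embryos in a group (%d vs %d)",
        st, length(a), length(b)), call. = FALSE)
      next
    }
    cmp <- compare_groups(a, b, metric = "representative_gap",
                          level = "per_embryo")
    rows[[st]] <- data.frame(
      stage_label = st,
      mean_a = cmp$mean_a, se_a = cmp$sd_a / sqrt(cmp$n_a), n_a = cmp$n_a,
      mean_b = cmp$mean_b, se_b = cmp$sd_b / sqrt(cmp$n_b), n_b = cmp$n_b,
      t_statistic = cmp$t_statistic, p_value = cmp$p_value,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    stop("no stage had at least 2 embryos per group", call. = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "groups") <- groups
  class(out) <- c("gap_timecourse", class(out))
  out
}

#' Synthetic bilateral-domain edges
#'
#' Small generator of `domain_edges` tables for testing the gap
#' statistic: per group and stage, each embryo's medial edges are two
#' near-vertical curves symmetric about x = 0 whose separation follows
#' the supplied per-stage mean gap plus embryo-level Gaussian variation
#' and a mild anterior taper. Deterministic given `seed`.
#'
#' @param stage_gaps named list: for each group, a named numeric vector
#'   of mean gaps (um) per stage label.
#' @param n_embryos embryos per group.
#' @param gap_sd between-embryo SD of the gap, um.
#' @param y_span AP extent of each edge curve, um (>= 400 so three
#'   points 200 um apart fit).
#' @param n_samples edge samples per curve.
#' @param taper gap narrowing from posterior to anterior end, um.
#' @param seed integer seed.
#' @return A `domain_edges` data frame with a `group` column.
#' @export
simulate_domain_edges <- function(stage_gaps, n_embryos = 4L, gap_sd = 10,
                                  y_span = 500, n_samples = 11L,
                                  taper = 20, seed = 1L) {
  stopifnot(is.list(stage_gaps), length(stage_gaps) >= 1L, y_span >= 400)
  with_local_seed(seed, {
    ys <- seq(0, y_span, length.out = n_samples)
    rows <- list()
    for (grp in names(stage_gaps)) {
      gaps <- stage_gaps[[grp]]
      for (i in seq_len(n_embryos)) {
        eid <- sprintf("%s_e%d", grp, i)
        jitter <- stats::rnorm(length(gaps), 0, gap_sd)
        for (j in seq_along(gaps)) {
          g <- max(gaps[j] + jitter[j], 2)
          # anterior (high y) end is 'taper' um narrower, floored at 0
          half <- pmax((g - taper * ys / y_span) / 2, 0)
          rows[[length(rows) + 1L]] <- data.frame(
            embryo_id = eid, group = grp, stage_label = names(gaps)[j],
            side = rep(c("left", "right"), each = length(ys)),
            y = rep(ys, 2L), x = c(-half, half), stringsAsFactors = FALSE)
        }
      }
    }
    as_domain_edges(do.call(rbind, c(rows, make.row.names = FALSE)))
  })
}
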