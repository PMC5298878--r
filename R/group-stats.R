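#' Per-embryo summaries of cell kinematics
#'
#' Arithmetic means of each kinematic metric over the cells of each
#' embryo, excluding undefined (missing) values per metric, plus the
#' share of cells showing no medial movement (`velocity_ml <= 0`).
#' Per-embryo means treat the embryo as the biological replicate, the
#' companion view to per-cell cohort statistics.
#'
#' @param kin a `cell_kinematics` table from [compute_kinematics()].
#' @return An `embryo_summary` data frame, one row per embryo.
#' @export
summarize_embryos <- function(kin) {
  stopifnot(is.data.frame(kin), nrow(kin) > 0L)
  metrics <- c("duration", "path_length", "displacement", "speed",
               "efficiency", "velocity_ml", "velocity_ap", "direction")
  rows <- lapply(split(seq_len(nrow(kin)), kin$embryo_id), function(i) {
    sub <- kin[i, , drop = FALSE]
    out <- data.frame(embryo_id = sub$embryo_id[1L], group = sub$group[1L],
                      n_cells = nrow(sub), stringsAsFactors = FALSE)
    for (m in metrics) {
      vals <- sub[[m]][!is.na(sub[[m]])]
      if (length(vals) == 0L) {
        message(sprintf("embryo '%s': no defined values for %s",
                        out$embryo_id, m))
        out[[paste0("mean_", m)]] <- NA_real_
      } else {
        out[[paste0("mean_", m)]] <- mean(vals)
      }
    }
    out$fraction_non_medial <- mean(sub$velocity_ml <= 0, na.rm = TRUE)
    out
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("embryo_summary", class(out))
  out
}

#' Direction histogram over [0, 180] degrees
#'
#' Bins net movement directions into `n_bins` equal angular bins
#' spanning [0, 180] (10 bins of 18 degrees by default), the counts
#' behind a rose plot. Bins are right-open except the last, which is
#' closed at 180, so both a purely medial (0) and a purely lateral (180)
#' direction are counted. Missing directions (stationary cells) are
#' excluded; counts sum to the number of cells with a defined direction.
#'
#' @param kin a `cell_kinematics` table (or any data frame with a
#'   `direction` column in degrees).
#' @param n_bins number of angular bins.
#' @param group optional cohort label stored on the result.
#' @return A `direction_histogram` list: `bin_edges` (length
#'   `n_bins + 1`), `counts`, `group`.
#' @export
direction_histogram <- function(kin, n_bins = 10L, group = NULL) {
  dirs <- kin$direction
  dirs <- dirs[!is.na(dirs)]
  if (length(dirs) == 0L) {
    stop("no defined directions to bin", call. = FALSE)
  }
  if (any(dirs < 0 | dirs > 180)) {
    stop("directions must lie in [0, 180] degrees", call. = FALSE)
  }
  edges <- seq(0, 180, length.out = n_bins + 1L)
  bin <- pmin(findInterval(dirs, edges), n_bins)  # last bin closed at 180
  counts <- tabulate(bin, nbins = n_bins)
  if (is.null(group) && !is.null(kin$group) && nrow(kin) > 0L) {
    g <- unique(kin$group)
    if (length(g) == 1L) group <- g
  }
  structure(list(bin_edges = edges, counts = counts, group = group),
            class = "direction_histogram")
}

#' @export
print.direction_histogram <- function(x, ...) {
  n <- length(x$counts)
  cat(sprintf("<direction_histogram> %d bins over [0, 180] deg%s\n", n,
              if (!is.null(x$group)) paste0(" (group: ", x$group, ")")
              else ""))
  lab <- sprintf("[%g,%g%s", x$bin_edges[-(n + 1L)], x$bin_edges[-1L],
                 c(rep(")", n - 1L), "]"))
  print(stats::setNames(x$counts, lab))
  invisible(x)
}

#' Two-sample comparison (unpaired Student's t-test)
#'
#' Classic pooled-variance two-sample t statistic with a two-tailed p
#' value on `n_a + n_b - 2` degrees of freedom, the test used for every
#' group contrast in this analysis. Welch's unequal-variance form is
#' available via `var_equal = FALSE`.
#'
#' @param a,b numeric vectors (each of length >= 2, finite).
#' @param metric optional metric name recorded on the result.
#' @param level `"per_cell"` or `"per_embryo"`, the aggregation level of
#'   the values being compared.
#' @param var_equal pool the variances (classic Student form)?
#' @return A `group_comparison` list: group means, SDs, ns,
#'   `t_statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(a, b, metric = NULL,
                           level = c("per_cell", "per_embryo"),
                           var_equal = TRUE) {
  level <- match.arg(level)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("group values must be finite", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    stop("degenerate input: zero variance in both groups with equal means",
         call. = FALSE)
  }
  fit <- stats::t.test(a, b, var.equal = var_equal,
                       alternative = "two.sided")
  structure(list(metric = metric, level = level,
                 mean_a = mean(a), mean_b = mean(b),
                 sd_a = stats::sd(a), sd_b = stats::sd(b),
                 n_a = length(a), n_b = length(b),
                 t_statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = unname(fit$p.value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s%s\n",
              if (!is.null(x$metric)) paste0(" ", x$metric) else "",
              paste0(" (", x$level, ")")))
  cat(sprintf("  group A: mean %.4g (sd %.4g, n %d)\n", x$mean_a, x$sd_a,
              x$n_a))
  cat(sprintf("  group B: mean %.4g (sd %.4g, n %d)\n", x$mean_b, x$sd_b,
              x$n_b))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g (two-tailed)\n",
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Share of cells without medial movement
#'
#' Fraction of cells whose net medial-lateral velocity is `<= 0`
#' (equivalently, net direction >= 90 degrees): the cells showing no
#' medial movement.
#'
#' @param kin a `cell_kinematics` table or a numeric vector of
#'   `velocity_ml` values.
#' @return A number in [0, 1].
#' @export
fraction_non_medial <- function(kin) {
  v <- if (is.data.frame(kin)) kin$velocity_ml else as.numeric(kin)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no defined velocity_ml values", call. = FALSE)
  mean(v <= 0)
}
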