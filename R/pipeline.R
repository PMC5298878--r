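#' Pipeline configuration
#'
#' Collects every tunable analysis option in one object, serializable to
#' YAML so a run can be reproduced exactly from its config file and seed.
#'
#' @param preset cohort preset name for simulation (`"wt"`,
#'   `"ref_mutant"`) or `NULL` when analysing supplied tracks.
#' @param seed integer seed recorded in all outputs.
#' @param var_equal pooled-variance t-test (classic Student form)?
#' @param non_medial_threshold velocity_ml cutoff (um/min) at or below
#'   which a cell counts as showing no medial movement.
#' @param n_direction_bins angular bins of the direction histogram.
#' @param gap_anchor `"centered"` or `"anterior"` placement of the gap
#'   sample points.
#' @param gap_spacing spacing of the gap sample points, um.
#' @param gap_n_points number of gap sample points.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preset = NULL, seed = 1L, var_equal = TRUE,
                            non_medial_threshold = 0,
                            n_direction_bins = 10L,
                            gap_anchor = "centered", gap_spacing = 200,
                            gap_n_points = 3L) {
  structure(list(preset = preset, seed = as.integer(seed),
                 var_equal = var_equal,
                 non_medial_threshold = non_medial_threshold,
                 n_direction_bins = as.integer(n_direction_bins),
                 gap_anchor = gap_anchor, gap_spacing = gap_spacing,
                 gap_n_points = as.integer(gap_n_points)),
            class = "pipeline_config")
}

#' Write / read a pipeline config as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `path` (write) or the config (read).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[!vapply(vals, is.null, logical(1L))])
}

# md5 of the serialized config, for provenance headers
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

provenance_lines <- function(config) {
  c(sprintf("#seed=%d", config$seed),
    sprintf("#config_md5=%s", config_hash(config)))
}

write_output_csv <- function(df, dest, config) {
  con <- file(dest, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_lines(config), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
  invisible(dest)
}

log_msg <- function(...) message("[cardiotrax] ", sprintf(...))

#' Simulate a cohort and write its track table
#'
#' Writes `tracks_<preset>.csv` (native dialect) and a JSON manifest
#' recording the preset, seed and config hash.
#'
#' @param preset preset name (`"wt"` or `"ref_mutant"`).
#' @param seed integer seed.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the tracks file path.
#' @export
cmd_simulate <- function(preset, seed = 1L, outdir = ".") {
  pre <- make_preset(preset, seed = seed)  # errors on unknown preset
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tracks <- simulate_cohort(pre)
  dest <- file.path(outdir, sprintf("tracks_%s.csv", pre$name))
  write_tracks(tracks, dest)
  cfg <- pipeline_config(preset = pre$name, seed = seed)
  manifest <- list(preset = pre$name, seed = seed,
                   config_md5 = config_hash(cfg),
                   n_embryos = nrow(pre$embryos),
                   n_cells = pre$total_cells, tracks_file = basename(dest))
  jsonlite::write_json(manifest, file.path(outdir, "simulate_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg("simulated %s cohort: %d embryos, %d cells -> %s", pre$name,
          nrow(pre$embryos), pre$total_cells, dest)
  invisible(dest)
}

#' Run the full trajectory analysis
#'
#' Complete-track filtering, drift correction, side alignment, AP
#' banding, per-cell kinematics, per-embryo summaries, direction
#' histograms and (when two groups are present) per-cell and per-embryo
#' group comparisons.
#'
#' @param tracks a [track_table()] or the path of a native-dialect CSV.
#' @param config a [pipeline_config()].
#' @return A `trajectory_analysis` list: `kinematics`,
#'   `embryo_summaries`, `histograms` (per group), `comparisons` (per
#'   metric, per level; NULL with one group), `filter_report`, `config`.
#' @export
analyze_tracks <- function(tracks, config = pipeline_config()) {
  if (is.character(tracks)) tracks <- read_tracks(tracks)
  stopifnot(inherits(tracks, "track_table"))
  filtered <- filter_complete_tracks(tracks)
  report <- attr(filtered, "filter_report")
  corrected <- drift_correct(filtered)
  aligned <- align_sides(corrected)
  banded <- split_ap_bands(aligned)
  kin <- compute_kinematics(banded)
  summaries <- summarize_embryos(kin)
  groups <- sort(unique(kin$group))
  histograms <- lapply(stats::setNames(groups, groups), function(g) {
    direction_histogram(kin[kin$group == g, , drop = FALSE],
                        n_bins = config$n_direction_bins, group = g)
  })
  comparisons <- NULL
  if (length(groups) == 2L) {
    metrics <- c("speed", "efficiency", "velocity_ml", "velocity_ap")
    comparisons <- list()
    for (m in metrics) {
      va <- kin[[m]][kin$group == groups[1L]]
      vb <- kin[[m]][kin$group == groups[2L]]
      comparisons[[paste0(m, "_per_cell")]] <-
        compare_groups(va[!is.na(va)], vb[!is.na(vb)], metric = m,
                       level = "per_cell", var_equal = config$var_equal)
    }
    ma <- summaries$mean_velocity_ml[summaries$group == groups[1L]]
    mb <- summaries$mean_velocity_ml[summaries$group == groups[2L]]
    if (length(ma) >= 2L && length(mb) >= 2L) {
      comparisons$velocity_ml_per_embryo <-
        compare_groups(ma, mb, metric = "velocity_ml",
                       level = "per_embryo", var_equal = config$var_equal)
    }
  }
  structure(list(kinematics = kin, embryo_summaries = summaries,
                 histograms = histograms, comparisons = comparisons,
                 filter_report = report, config = config),
            class = "trajectory_analysis")
}

#' @export
print.trajectory_analysis <- function(x, ...) {
  cat(sprintf("<trajectory_analysis> %d cells, %d embryo(s), group(s): %s\n",
              nrow(x$kinematics),
              nrow(x$embryo_summaries),
              paste(names(x$histograms), collapse = ", ")))
  for (g in names(x$histograms)) {
    sel <- x$kinematics$group == g
    cat(sprintf(
      "  %s: mean speed %.3f um/min, mean ML velocity %.3f um/min, non-medial %.2f\n",
      g, mean(x$kinematics$speed[sel], na.rm = TRUE),
      mean(x$kinematics$velocity_ml[sel], na.rm = TRUE),
      fraction_non_medial(x$kinematics[sel, , drop = FALSE])))
  }
  if (!is.null(x$comparisons$velocity_ml_per_cell)) {
    cmp <- x$comparisons$velocity_ml_per_cell
    cat(sprintf("  ML velocity (per cell): t = %.3f, p = %.3g\n",
                cmp$t_statistic, cmp$p_value))
  }
  invisible(x)
}

#' Analyse tracks and write all outputs
#'
#' Runs [analyze_tracks()] and writes per-cell metrics, per-embryo
#' summaries, histogram counts, group comparisons and the filter report
#' as CSVs (each with a provenance header carrying the seed and config
#' hash), plus optional figures.
#'
#' @param tracks track table or native CSV path.
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param figures also write PNG figures?
#' @return Invisibly, the `trajectory_analysis`.
#' @export
cmd_analyze <- function(tracks, config = pipeline_config(), outdir = ".",
                        figures = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- analyze_tracks(tracks, config)
  write_output_csv(res$kinematics, file.path(outdir, "cell_kinematics.csv"),
                   config)
  write_output_csv(res$embryo_summaries,
                   file.path(outdir, "embryo_summaries.csv"), config)
  hist_df <- do.call(rbind, lapply(names(res$histograms), function(g) {
    h <- res$histograms[[g]]
    data.frame(group = g, bin_start = h$bin_edges[-length(h$bin_edges)],
               bin_end = h$bin_edges[-1L], count = h$counts,
               stringsAsFactors = FALSE)
  }))
  write_output_csv(hist_df, file.path(outdir, "direction_histogram.csv"),
                   config)
  if (!is.null(res$comparisons)) {
    cmp_df <- do.call(rbind, lapply(names(res$comparisons), function(nm) {
      cmp <- res$comparisons[[nm]]
      data.frame(comparison = nm, metric = cmp$metric, level = cmp$level,
                 mean_a = cmp$mean_a, mean_b = cmp$mean_b,
                 sd_a = cmp$sd_a, sd_b = cmp$sd_b,
                 n_a = cmp$n_a, n_b = cmp$n_b,
                 t_statistic = cmp$t_statistic, df = cmp$df,
                 p_value = cmp$p_value, stringsAsFactors = FALSE)
    }))
    write_output_csv(cmp_df, file.path(outdir, "group_comparisons.csv"),
                     config)
  }
  write_output_csv(res$filter_report, file.path(outdir, "filter_report.csv"),
                   config)
  if (figures) {
    for (g in names(res$histograms)) {
      grDevices::png(file.path(outdir, sprintf("rose_%s.png", g)),
                     width = 600, height = 400)
      plot(res$histograms[[g]])
      grDevices::dev.off()
    }
    grDevices::png(file.path(outdir, "velocity_ml_dots.png"),
                   width = 600, height = 400)
    plot_metric_dots(res$kinematics$velocity_ml, res$kinematics$group,
                     ylab = "ML velocity (µm/min)",
                     main = "Medial-lateral velocity per cell")
    grDevices::dev.off()
  }
  log_msg("analysis written to %s (%d cells, %d embryos)", outdir,
          nrow(res$kinematics), nrow(res$embryo_summaries))
  invisible(res)
}

#' Measure bilateral-domain gaps and their time course
#'
#' @param edges a `domain_edges` table or CSV path.
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param figures also write the divergence plot?
#' @return Invisibly, a list with `gaps` and (when two groups are
#'   present) `timecourse`.
#' @export
cmd_gap <- function(edges, config = pipeline_config(), outdir = ".",
                    figures = FALSE) {
  if (is.character(edges)) edges <- read_domain_edges(edges)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gaps <- measure_gaps(edges, anchor = config$gap_anchor,
                       spacing = config$gap_spacing,
                       n_points = config$gap_n_points)
  write_output_csv(gaps, file.path(outdir, "gap_measurements.csv"), config)
  tc <- NULL
  if (!all(is.na(gaps$group)) &&
      length(unique(gaps$group[!is.na(gaps$group)])) == 2L) {
    tc <- gap_timecourse(gaps)
    write_output_csv(tc, file.path(outdir, "gap_timecourse.csv"), config)
    if (figures) {
      grDevices::png(file.path(outdir, "gap_timecourse.png"),
                     width = 600, height = 400)
      plot(tc)
      grDevices::dev.off()
    }
  }
  log_msg("gap statistics written to %s (%d measurements)", outdir,
          nrow(gaps))
  invisible(list(gaps = gaps, timecourse = tc))
}
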