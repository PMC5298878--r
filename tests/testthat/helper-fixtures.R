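# In-code fixtures used across the suite.

# Build a track_table from a list of tracks; each element is
# list(id, side, class, x, y[, z]) with positions sampled at t_index
# 0..(length(x)-1).
toy_tracks <- function(tracks, embryo_id = "e1", group = "wt",
                       midline_x = 0, dt = 4, validate = TRUE) {
  rows <- lapply(tracks, function(tr) {
    n <- length(tr$x)
    stopifnot(length(tr$y) == n)
    data.frame(
      embryo_id = embryo_id, group = group, track_id = tr$id,
      cell_class = if (is.null(tr$class)) "cardiomyocyte" else tr$class,
      side = if (is.null(tr$side)) "left" else tr$side,
      t_index = if (is.null(tr$t_index)) 0:(n - 1L) else tr$t_index,
      t = (if (is.null(tr$t_index)) 0:(n - 1L) else tr$t_index) * dt,
      x = tr$x, y = tr$y, z = if (is.null(tr$z)) rep(0, n) else tr$z,
      stringsAsFactors = FALSE)
  })
  track_table(do.call(rbind, rows), midline_x = midline_x, dt = dt,
              validate = validate)
}

# A stationary reference track at the origin, n timepoints.
stationary_ref <- function(n, x = 0, y = 100) {
  list(id = "ref", class = "reference", side = "none",
       x = rep(x, n), y = rep(y, n))
}

# Run the full preprocessing + kinematics chain.
pipeline_kinematics <- function(tracks) {
  compute_kinematics(split_ap_bands(align_sides(drift_correct(
    filter_complete_tracks(tracks)))))
}

# Random multi-cell embryo with a moving reference, for property tests.
random_embryo_tracks <- function(n_cells = 6L, n_tp = 11L, midline_x = 50,
                                 dt = 4) {
  tracks <- lapply(seq_len(n_cells), function(i) {
    side <- if (i %% 2L == 0L) "right" else "left"
    x0 <- midline_x + (if (side == "left") -60 else 60) + rnorm(1, 0, 5)
    list(id = sprintf("c%02d", i), side = side,
         x = x0 + cumsum(c(0, rnorm(n_tp - 1L, 0, 1.5))),
         y = rnorm(1, 0, 20) + cumsum(c(0, rnorm(n_tp - 1L, 0.2, 1.5))))
  })
  ref <- list(id = "ref", class = "reference", side = "none",
              x = midline_x + cumsum(c(0, rnorm(n_tp - 1L, 0.3, 0.5))),
              y = 150 + cumsum(c(0, rnorm(n_tp - 1L, -0.2, 0.5))))
  toy_tracks(c(tracks, list(ref)), midline_x = midline_x, dt = dt)
}

# Parallel straight bilateral edges, for gap-statistic tests.
straight_edges <- function(left_x = -50, right_x = 50, y = seq(0, 400, 100),
                           embryo_id = "e1", stage = "16s", group = NULL) {
  df <- data.frame(embryo_id = embryo_id, stage_label = stage,
                   side = rep(c("left", "right"), each = length(y)),
                   y = rep(y, 2L), x = c(rep(left_x, length(y)),
                                         rep(right_x, length(y))),
                   stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- group
  as_domain_edges(df)
}

# Reflect a track table about its midline and swap left/right labels.
mirror_tracks <- function(tracks) {
  midline_x <- attr(tracks, "midline_x")
  out <- as.data.frame(tracks)
  out$x <- 2 * midline_x - out$x
  out$side <- c(left = "right", right = "left", none = "none")[out$side]
  track_table(out, midline_x = midline_x, dt = attr(tracks, "dt"))
}
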