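#' Net movement direction
#'
#' Direction of a net XY displacement in the aligned frame, as the
#' quadrant-aware angle between the vector `(dxm, |dy|)` and the medial
#' axis, in degrees within [0, 180]: 0 = purely medial (toward the
#' midline), 90 = purely anterior-posterior, 180 = purely lateral. Using
#' the absolute AP displacement folds the two AP directions together, so
#' the angle only distinguishes medial from lateral movement; the
#' single-argument arctangent of |dy|/dxm cannot, which is why the
#' two-argument form is used.
#'
#' @param dxm net medial displacement, um (+ = toward midline).
#' @param dy net anterior-posterior displacement, um.
#' @return Angle(s) in degrees in [0, 180]; vectorized.
#' @export
net_direction <- function(dxm, dy) {
  if (length(dxm) != length(dy)) stop("dxm and dy must have equal length",
                                      call. = FALSE)
  if (any(dxm == 0 & dy == 0)) {
    stop("direction is undefined for a zero displacement vector",
         call. = FALSE)
  }
  atan2(abs(dy), dxm) * 180 / pi
}

#' Per-cell kinematic metrics
#'
#' Computes, for every complete cardiomyocyte track, the track-level
#' movement metrics in the aligned XY frame `(xm, y)`:
#' \describe{
#'   \item{duration}{tracked time span, min.}
#'   \item{path_length}{polygonal path length over the sampled positions
#'     ("distance"), um; no smoothing.}
#'   \item{displacement}{straight-line chord from first to last
#'     position, um.}
#'   \item{speed}{path_length / duration, um/min.}
#'   \item{efficiency}{displacement / path_length, in [0, 1]; 1 = a
#'     perfectly straight path.}
#'   \item{velocity_ml}{net medial displacement / duration, um/min
#'     (+ = toward the midline).}
#'   \item{velocity_ap}{net anterior-posterior displacement / duration,
#'     um/min.}
#'   \item{direction}{[net_direction()] of the net displacement, degrees
#'     in [0, 180].}
#' }
#' Net quantities use the first and last timepoint of each track. For a
#' track that never moves (path_length 0), speed is 0 and efficiency and
#' direction are reported as missing rather than 0, so cohort means are
#' not biased; the count of such tracks is attached as the
#' `n_stationary` attribute.
#'
#' @param tracks an aligned, complete [track_table()] (see
#'   [filter_complete_tracks()], [drift_correct()], [align_sides()]).
#' @return A `cell_kinematics` data frame, one row per cardiomyocyte.
#' @export
compute_kinematics <- function(tracks) {
  stopifnot(inherits(tracks, "track_table"))
  if (!isTRUE(attr(tracks, "aligned")) || is.null(tracks$xm)) {
    stop("tracks must be drift-corrected and aligned (xm column present)",
         call. = FALSE)
  }
  cells <- tracks[tracks$cell_class == "cardiomyocyte", , drop = FALSE]
  idx <- split_tracks(cells)
  rows <- lapply(idx, function(i) {
    tr <- cells[i, , drop = FALSE]
    tr <- tr[order(tr$t_index), , drop = FALSE]
    duration <- tr$t[nrow(tr)] - tr$t[1L]
    if (duration <= 0) {
      stop(sprintf("track '%s' (embryo '%s') has zero duration",
                   tr$track_id[1L], tr$embryo_id[1L]), call. = FALSE)
    }
    steps <- sqrt(diff(tr$xm)^2 + diff(tr$y)^2)
    path_length <- sum(steps)
    dxm <- tr$xm[nrow(tr)] - tr$xm[1L]
    dy <- tr$y[nrow(tr)] - tr$y[1L]
    displacement <- sqrt(dxm^2 + dy^2)
    stationary <- path_length == 0
    data.frame(
      embryo_id = tr$embryo_id[1L],
      group = tr$group[1L],
      track_id = tr$track_id[1L],
      side = tr$side[1L],
      ap_band = if (!is.null(tr$ap_band)) tr$ap_band[1L] else NA_character_,
      duration = duration,
      path_length = path_length,
      displacement = displacement,
      speed = path_length / duration,
      efficiency = if (stationary) NA_real_ else displacement / path_length,
      velocity_ml = dxm / duration,
      velocity_ap = dy / duration,
      direction = if (displacement == 0) NA_real_ else net_direction(dxm, dy),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out <- out[order(out$embryo_id, out$track_id), , drop = FALSE]
  rownames(out) <- NULL
  n_stationary <- sum(out$path_length == 0)
  if (n_stationary > 0L) {
    message(n_stationary,
            " stationary track(s): efficiency/direction set to NA")
  }
  attr(out, "n_stationary") <- n_stationary
  class(out) <- c("cell_kinematics", class(out))
  out
}

#' @export
print.cell_kinematics <- function(x, ...) {
  cat(sprintf("<cell_kinematics> %d cell(s) in %d embryo(s)\n",
              nrow(x), length(unique(x$embryo_id))))
  for (m in c("speed", "efficiency", "velocity_ml", "velocity_ap")) {
    cat(sprintf("  mean %-12s %8.4f\n", m, mean(x[[m]], na.rm = TRUE)))
  }
  invisible(as.data.frame(x))
}
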