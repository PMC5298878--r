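#' Drift-correct tracks against the reference landmark
#'
#' For each embryo, subtracts the reference track's cumulative
#' displacement since t_index 0 from every cell position at the matching
#' timepoint (positions are corrected, not velocities; t0 positions are
#' unchanged). This removes any displacement field shared by the
#' reference and the cells — stage or imaging drift — exactly. The
#' reference defines the frame: its own biological motion (the slight
#' posterior retraction of the notochord tip) is part of the correction
#' by convention, not modelled out separately. Reference rows are
#' dropped from the output.
#'
#' @param tracks a [track_table()]; each embryo must contain exactly one
#'   complete reference track.
#' @return The corrected `track_table` (flag `drift_corrected = TRUE`,
#'   reference rows removed).
#' @export
drift_correct <- function(tracks) {
  stopifnot(inherits(tracks, "track_table"))
  out <- as.data.frame(tracks)
  for (eid in unique(out$embryo_id)) {
    emb <- out$embryo_id == eid
    ref <- which(emb & out$cell_class == "reference")
    if (length(ref) == 0L) {
      stop(sprintf("embryo '%s' has no reference track; cannot drift-correct",
                   eid), call. = FALSE)
    }
    t_all <- sort(unique(out$t_index[emb]))
    if (!setequal(out$t_index[ref], t_all) ||
        length(ref) != length(t_all)) {
      stop(sprintf(
        "embryo '%s': reference track is incomplete; cannot drift-correct",
        eid), call. = FALSE)
    }
    ref <- ref[order(out$t_index[ref])]
    # cumulative displacement of the reference since t_index 0
    disp_x <- out$x[ref] - out$x[ref][1L]
    disp_y <- out$y[ref] - out$y[ref][1L]
    disp_z <- out$z[ref] - out$z[ref][1L]
    cells <- which(emb & out$cell_class == "cardiomyocyte")
    pos <- match(out$t_index[cells], t_all)
    out$x[cells] <- out$x[cells] - disp_x[pos]
    out$y[cells] <- out$y[cells] - disp_y[pos]
    out$z[cells] <- out$z[cells] - disp_z[pos]
  }
  out <- out[out$cell_class != "reference", , drop = FALSE]
  rownames(out) <- NULL
  out <- track_table(out, midline_x = attr(tracks, "midline_x"),
                     dt = attr(tracks, "dt"), validate = FALSE)
  attr(out, "drift_corrected") <- TRUE
  attr(out, "aligned") <- isTRUE(attr(tracks, "aligned"))
  out
}

#' Align left and right sides into a common medial coordinate
#'
#' Adds the medial coordinate `xm`, defined by mirroring about the
#' declared midline: `xm = midline_x - x` for right-side cells and
#' `xm = x - midline_x` for left-side cells, so movement toward the
#' midline strictly increases `xm` on both sides. The midline is table
#' metadata (an anatomical landmark), never estimated from the tracks.
#'
#' @param tracks a drift-corrected [track_table()].
#' @return The table with an `xm` column and flag `aligned = TRUE`.
#' @export
align_sides <- function(tracks) {
  stopifnot(inherits(tracks, "track_table"))
  if (!isTRUE(attr(tracks, "drift_corrected"))) {
    stop("tracks must be drift-corrected before side alignment", call. = FALSE)
  }
  midline_x <- attr(tracks, "midline_x")
  if (is.null(midline_x) || !is.finite(midline_x)) {
    stop("midline_x metadata is required for side alignment", call. = FALSE)
  }
  cm <- tracks$cell_class == "cardiomyocyte"
  bad <- cm & !(tracks$side %in% c("left", "right"))
  if (any(bad)) {
    stop("cardiomyocyte track(s) without a left/right side label: ",
         paste(unique(tracks$track_id[bad]), collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(tracks)
  out$xm <- ifelse(out$side == "right", midline_x - out$x, out$x - midline_x)
  out <- track_table(out, midline_x = midline_x, dt = attr(tracks, "dt"),
                     validate = FALSE)
  attr(out, "drift_corrected") <- TRUE
  attr(out, "aligned") <- TRUE
  out
}

#' Label anterior-posterior bands
#'
#' Per embryo and side, labels cells `top` / `middle` / `bottom` by
#' tertiles of their initial (t_index 0) y position; the most anterior
#' cells (largest y) are `top`. Bands are fixed for the whole timelapse.
#' Cells are ranked by initial y with ties broken by `track_id` order;
#' rank r of n maps to band `round(2 * (r - 1) / (n - 1))` (0 = top,
#' 2 = bottom), so 9 distinct cells split 3/3/3 and 2 cells get top and
#' bottom with middle empty. A single cell is labelled `middle`.
#'
#' @param tracks an aligned [track_table()].
#' @return The table with an `ap_band` column.
#' @export
split_ap_bands <- function(tracks) {
  stopifnot(inherits(tracks, "track_table"))
  if (!isTRUE(attr(tracks, "aligned"))) {
    stop("tracks must be aligned before AP banding", call. = FALSE)
  }
  out <- as.data.frame(tracks)
  out$ap_band <- NA_character_
  first <- out[out$t_index == 0 & out$cell_class == "cardiomyocyte", ]
  bands <- c("top", "middle", "bottom")
  for (key in unique(paste(first$embryo_id, first$side, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sel <- first$embryo_id == parts[1L] & first$side == parts[2L]
    ids <- first$track_id[sel]
    y0 <- first$y[sel]
    ord <- order(-y0, ids)  # anterior first; ties by track_id
    n <- length(ids)
    band_idx <- if (n == 1L) 1L else round(2 * (seq_len(n) - 1) / (n - 1))
    lab <- structure(bands[band_idx + 1L], names = ids[ord])
    rows <- out$embryo_id == parts[1L] & out$side == parts[2L] &
      out$cell_class == "cardiomyocyte"
    out$ap_band[rows] <- lab[out$track_id[rows]]
  }
  res <- track_table(out, midline_x = attr(tracks, "midline_x"),
                     dt = attr(tracks, "dt"), validate = FALSE)
  attr(res, "drift_corrected") <- isTRUE(attr(tracks, "drift_corrected"))
  attr(res, "aligned") <- TRUE
  res
}
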