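#' Cell-track tables
#'
#' A `track_table` is a long-format data frame with one row per tracked
#' object per timepoint, the container consumed and produced by every step
#' of the trajectory pipeline. Columns:
#'
#' \describe{
#'   \item{embryo_id}{character, embryo identifier.}
#'   \item{group}{character, cohort label (e.g. `"wt"`, `"mutant"`).}
#'   \item{track_id}{character, unique object identifier within an embryo.}
#'   \item{cell_class}{`"cardiomyocyte"` or `"reference"` (the landmark
#'     track used for drift correction; exactly one per embryo).}
#'   \item{side}{`"left"`, `"right"`, or `"none"` (reference tracks only).}
#'   \item{t_index}{integer timepoint index starting at 0.}
#'   \item{t}{time in minutes, equal to `t_index * dt`.}
#'   \item{x}{medial-lateral position, micrometres.}
#'   \item{y}{anterior-posterior position, micrometres (+ = anterior).}
#'   \item{z}{dorsal-ventral position, micrometres.}
#' }
#'
#' Table-level metadata are carried as attributes: `midline_x` (the
#' anatomical midline x-coordinate, micrometres) and `dt` (sampling
#' interval, minutes). Preprocessing adds the logical flags
#' `drift_corrected` and `aligned`, the medial coordinate column `xm`
#' (+ = toward the midline, for either side) and the `ap_band` label.
#'
#' @param data data frame with the columns listed above.
#' @param midline_x numeric scalar, midline x-coordinate in micrometres.
#' @param dt numeric scalar, sampling interval in minutes.
#' @param validate logical; run [validate_track_table()]?
#' @return A `track_table` (data frame subclass).
#' @export
track_table <- function(data, midline_x, dt, validate = TRUE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in c("embryo_id", "group", "track_id", "cell_class", "side")) {
    if (col %in% names(data)) data[[col]] <- as.character(data[[col]])
  }
  attr(data, "midline_x") <- as.numeric(midline_x)
  attr(data, "dt") <- as.numeric(dt)
  if (is.null(attr(data, "drift_corrected"))) attr(data, "drift_corrected") <- FALSE
  if (is.null(attr(data, "aligned"))) attr(data, "aligned") <- FALSE
  class(data) <- unique(c("track_table", class(data)))
  if (validate) validate_track_table(data)
  data
}

TRACK_COLUMNS <- c("embryo_id", "group", "track_id", "cell_class", "side",
                   "t_index", "t", "x", "y", "z")

#' Validate a track table
#'
#' Checks the schema and the structural invariants: required columns,
#' uniqueness of (embryo_id, track_id, t_index), `t = t_index * dt`,
#' at most one reference track per embryo, and `side == "none"` exactly
#' for reference tracks. A missing reference track is reported as a
#' warning (drift correction will refuse later), not an error.
#'
#' @param x a `track_table`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_track_table <- function(x) {
  missing_cols <- setdiff(TRACK_COLUMNS, names(x))
  if (length(missing_cols) > 0L) {
    stop("track table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(attr(x, "midline_x")) || is.null(attr(x, "dt"))) {
    stop("track table must carry 'midline_x' and 'dt' metadata", call. = FALSE)
  }
  if (nrow(x) == 0L) return(invisible(x))
  key <- paste(x$embryo_id, x$track_id, x$t_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), c("embryo_id", "track_id", "t_index")][1L, ]
    stop(sprintf(
      "duplicate (track_id, t_index): embryo '%s', track '%s', t_index %d",
      dup$embryo_id, dup$track_id, dup$t_index), call. = FALSE)
  }
  dt <- attr(x, "dt")
  if (any(abs(x$t - x$t_index * dt) > 1e-8)) {
    stop("column 't' must equal t_index * dt", call. = FALSE)
  }
  bad_class <- setdiff(unique(x$cell_class), c("cardiomyocyte", "reference"))
  if (length(bad_class) > 0L) {
    stop("unknown cell_class value(s): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  bad_side <- setdiff(unique(x$side), c("left", "right", "none"))
  if (length(bad_side) > 0L) {
    stop("unknown side value(s): ", paste(bad_side, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$side == "none" & x$cell_class != "reference")) {
    stop("side = 'none' is reserved for reference tracks", call. = FALSE)
  }
  if (any(x$cell_class == "reference" & x$side != "none")) {
    stop("reference tracks must have side = 'none'", call. = FALSE)
  }
  for (eid in unique(x$embryo_id)) {
    nref <- length(unique(x$track_id[x$embryo_id == eid &
                                       x$cell_class == "reference"]))
    if (nref > 1L) {
      stop(sprintf("embryo '%s' has %d reference tracks (expected one)",
                   eid, nref), call. = FALSE)
    }
    if (nref == 0L) {
      warning(sprintf(
        "embryo '%s' has no reference track; drift correction will fail",
        eid), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.track_table <- function(x, ...) {
  n_emb <- length(unique(x$embryo_id))
  cm <- x$cell_class == "cardiomyocyte"
  n_cells <- length(unique(paste(x$embryo_id[cm], x$track_id[cm])))
  cat(sprintf(
    "<track_table> %d rows: %d cardiomyocyte track(s) in %d embryo(s)\n",
    nrow(x), n_cells, n_emb))
  cat(sprintf("  midline_x = %g um, dt = %g min", attr(x, "midline_x"),
              attr(x, "dt")))
  flags <- c(if (isTRUE(attr(x, "drift_corrected"))) "drift-corrected",
             if (isTRUE(attr(x, "aligned"))) "aligned")
  if (length(flags)) cat(" [", paste(flags, collapse = ", "), "]", sep = "")
  cat("\n")
  if (nrow(x) > 0L) {
    print.data.frame(utils::head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  }
  invisible(x)
}

# carry metadata through row subsetting
#' @export
`[.track_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in c("midline_x", "dt", "drift_corrected", "aligned")) {
      attr(out, a) <- attr(x, a)
    }
    class(out) <- unique(c("track_table", class(out)))
  }
  out
}

# internal: per-(embryo, track) split preserving order
split_tracks <- function(x) {
  split(seq_len(nrow(x)),
        list(embryo = x$embryo_id, track = x$track_id), drop = TRUE)
}
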