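#' Read a cell-track table
#'
#' Two dialects are supported. The native dialect is a plain CSV with the
#' fixed header `embryo_id, group, track_id, cell_class, side, t_index, t,
#' x, y, z` preceded by comment lines `#midline_x=<um>` and `#dt=<min>`
#' carrying the table metadata. The `imaris_export` dialect accepts a
#' generic position/time/track export (header synonyms such as
#' `Position X` / `PosX` / `x`, `Time` / `t_index`, `TrackID` /
#' `Parent` / `track_id`) and requires a companion mapping CSV giving, for
#' each `track_id`, its `embryo_id`, `group`, `cell_class` and `side`;
#' positions are assumed to be in micrometres and time in frame indices.
#'
#' @param source path to the track CSV.
#' @param dialect `"native_csv"` or `"imaris_export"`.
#' @param mapping path to the companion mapping CSV (imaris_export only).
#' @param midline_x,dt metadata, required for `imaris_export` (the native
#'   dialect stores them in the file header).
#' @return A validated [track_table()].
#' @export
read_tracks <- function(source, dialect = c("native_csv", "imaris_export"),
                        mapping = NULL, midline_x = NULL, dt = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) {
    stop("track file not found: ", source, call. = FALSE)
  }
  if (dialect == "native_csv") {
    read_tracks_native(source)
  } else {
    read_tracks_imaris(source, mapping, midline_x, dt)
  }
}

read_tracks_native <- function(source) {
  head_lines <- readLines(source, n = 10L)
  meta <- grep("^#", head_lines, value = TRUE)
  get_meta <- function(name) {
    hit <- grep(paste0("^#", name, "="), meta, value = TRUE)
    if (length(hit) != 1L) {
      stop("native track CSV must carry a single '#", name, "=' header line",
           call. = FALSE)
    }
    as.numeric(sub(paste0("^#", name, "="), "", hit))
  }
  midline_x <- get_meta("midline_x")
  dt <- get_meta("dt")
  data <- utils::read.csv(source, comment.char = "#",
                          colClasses = c(embryo_id = "character",
                                         group = "character",
                                         track_id = "character",
                                         cell_class = "character",
                                         side = "character"),
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(TRACK_COLUMNS, names(data))
  if (length(missing_cols) > 0L) {
    stop("track CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  track_table(data[TRACK_COLUMNS], midline_x = midline_x, dt = dt)
}

# header synonyms accepted from generic Imaris-style exports
IMARIS_SYNONYMS <- list(
  x = c("x", "position.x", "position_x", "posx"),
  y = c("y", "position.y", "position_y", "posy"),
  z = c("z", "position.z", "position_z", "posz"),
  t_index = c("t_index", "time", "timepoint", "frame"),
  track_id = c("track_id", "trackid", "parent", "id")
)

read_tracks_imaris <- function(source, mapping, midline_x, dt) {
  if (is.null(mapping)) {
    stop("the imaris_export dialect requires a companion 'mapping' CSV ",
         "annotating each track_id with embryo_id, group, cell_class, side",
         call. = FALSE)
  }
  if (is.null(midline_x) || is.null(dt)) {
    stop("the imaris_export dialect requires 'midline_x' and 'dt'",
         call. = FALSE)
  }
  raw <- utils::read.csv(source, stringsAsFactors = FALSE, check.names = TRUE)
  lower <- tolower(gsub("[ .]+", ".", names(raw)))
  pick <- function(field) {
    idx <- which(lower %in% IMARIS_SYNONYMS[[field]])
    if (length(idx) == 0L) {
      stop("imaris export is missing a recognizable '", field, "' column",
           call. = FALSE)
    }
    raw[[idx[1L]]]
  }
  map <- utils::read.csv(mapping, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("track_id", "embryo_id", "group", "cell_class", "side")
  missing_cols <- setdiff(need, names(map))
  if (length(missing_cols) > 0L) {
    stop("mapping CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  track_id <- as.character(pick("track_id"))
  hit <- match(track_id, map$track_id)
  if (anyNA(hit)) {
    stop("mapping CSV has no annotation for track_id(s): ",
         paste(unique(track_id[is.na(hit)]), collapse = ", "), call. = FALSE)
  }
  t_index <- as.integer(pick("t_index"))
  t_index <- t_index - min(t_index)  # Imaris time is often 1-based
  data <- data.frame(
    embryo_id = map$embryo_id[hit],
    group = map$group[hit],
    track_id = track_id,
    cell_class = map$cell_class[hit],
    side = map$side[hit],
    t_index = t_index,
    t = t_index * dt,
    x = as.numeric(pick("x")),
    y = as.numeric(pick("y")),
    z = as.numeric(pick("z")),
    stringsAsFactors = FALSE
  )
  track_table(data, midline_x = midline_x, dt = dt)
}

#' Write a track table in the native CSV dialect
#'
#' Lossless serialization: metadata in `#midline_x=` / `#dt=` header
#' comment lines, then the fixed column order. [read_tracks()] on the
#' result reproduces the input table.
#'
#' @param tracks a [track_table()].
#' @param dest destination path.
#' @return `dest`, invisibly.
#' @export
write_tracks <- function(tracks, dest) {
  stopifnot(inherits(tracks, "track_table"))
  con <- file(dest, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("#midline_x=%.10g", attr(tracks, "midline_x")),
               sprintf("#dt=%.10g", attr(tracks, "dt"))), con)
  df <- as.data.frame(tracks)[, TRACK_COLUMNS, drop = FALSE]
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(dest)
}

#' Keep only complete tracks
#'
#' Retains tracks observed at every timepoint index from 0 to the maximum
#' t_index of their embryo, the inclusion rule used for all downstream
#' kinematics (net metrics are only comparable across cells observed over
#' the same window). Incomplete tracks are dropped and counted.
#'
#' @param tracks a [track_table()].
#' @return The filtered `track_table`, with a `filter_report` attribute:
#'   a data frame of retained/dropped track counts per embryo.
#' @export
filter_complete_tracks <- function(tracks) {
  stopifnot(inherits(tracks, "track_table"))
  if (nrow(tracks) == 0L) {
    attr(tracks, "filter_report") <- data.frame(
      embryo_id = character(), retained = integer(), dropped = integer(),
      stringsAsFactors = FALSE)
    return(tracks)
  }
  keep <- logical(nrow(tracks))
  report <- list()
  for (eid in unique(tracks$embryo_id)) {
    emb <- tracks$embryo_id == eid
    full_range <- 0:max(tracks$t_index[emb])
    retained <- 0L
    dropped <- 0L
    for (tid in unique(tracks$track_id[emb])) {
      rows <- which(emb & tracks$track_id == tid)
      complete <- length(rows) == length(full_range) &&
        setequal(tracks$t_index[rows], full_range)
      if (complete) {
        keep[rows] <- TRUE
        retained <- retained + 1L
      } else {
        dropped <- dropped + 1L
      }
    }
    report[[eid]] <- data.frame(embryo_id = eid, retained = retained,
                                dropped = dropped, stringsAsFactors = FALSE)
  }
  out <- tracks[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no complete tracks retained", call. = FALSE)
  }
  attr(out, "filter_report") <- do.call(rbind, c(report,
                                                 make.row.names = FALSE))
  out
}

#' Read a bilateral-domain edge table
#'
#' Edge tables give, per embryo and developmental stage, the medial edge
#' of the left and right bilateral domains as curves sampled in y
#' (anterior-posterior, micrometres). CSV columns: `embryo_id`,
#' `stage_label`, `side` (left/right), `y`, `x`; an optional `group`
#' column labels the cohort for time-course comparisons.
#'
#' @param source path to the edges CSV.
#' @return A `domain_edges` data frame.
#' @export
read_domain_edges <- function(source) {
  if (!file.exists(source)) {
    stop("edge file not found: ", source, call. = FALSE)
  }
  data <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("embryo_id", "stage_label", "side", "y", "x")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    stop("edge CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_domain_edges(data)
}

#' Construct a domain_edges table
#'
#' @param data data frame with columns `embryo_id`, `stage_label`, `side`
#'   (`"left"`/`"right"`), `y`, `x` and optionally `group`.
#' @return A validated `domain_edges` data frame.
#' @export
as_domain_edges <- function(data) {
  stopifnot(is.data.frame(data))
  bad_side <- setdiff(unique(data$side), c("left", "right"))
  if (length(bad_side) > 0L) {
    stop("domain edges side must be 'left' or 'right'; got: ",
         paste(bad_side, collapse = ", "), call. = FALSE)
  }
  for (key in unique(paste(data$embryo_id, data$stage_label, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sel <- data$embryo_id == parts[1L] & data$stage_label == parts[2L]
    for (s in c("left", "right")) {
      n <- sum(sel & data$side == s)
      if (n < 2L) {
        stop(sprintf(
          "embryo '%s' stage '%s': %s edge needs >= 2 samples (has %d)",
          parts[1L], parts[2L], s, n), call. = FALSE)
      }
    }
  }
  class(data) <- unique(c("domain_edges", class(data)))
  data
}

#' Write a domain_edges table as CSV
#' @param edges a `domain_edges` data frame.
#' @param dest destination path.
#' @return `dest`, invisibly.
#' @export
write_domain_edges <- function(edges, dest) {
  utils::write.csv(as.data.frame(edges), dest, row.names = FALSE)
  invisible(dest)
}
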