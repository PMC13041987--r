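#' Read a label movie from a multi-page TIFF
#'
#' Accepts uncompressed single-channel TIFF stacks with integer pixels
#' (8/16/32-bit, signed or unsigned). A single 2-D image is promoted to a
#' movie with `T = 1`. Float-valued TIFFs are rejected: probability and
#' intensity movies go through [read_probability_movie()] /
#' [read_intensity_movie()].
#'
#' @param path TIFF file.
#' @param pixel_size,frame_interval physical calibration, stored on the
#'   returned object (micrometres per pixel, minutes per frame).
#' @return a [label_movie()].
#' @export
read_label_movie <- function(path, pixel_size = 1.0, frame_interval = 1.0) {
  pages <- read_tiff_pages(path)
  if (any(vapply(pages, function(p) p$sample_format == 3L, logical(1))))
    stop_data("label movie must have integer pixels, got float TIFF: ", path)
  arr <- pages_to_array(pages)
  storage.mode(arr) <- "integer"
  label_movie(arr, pixel_size = pixel_size, frame_interval = frame_interval)
}

pages_to_array <- function(pages) {
  dims <- vapply(pages, function(p) dim(p$data), integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    stop_data("TIFF pages have inconsistent dimensions")
  h <- dims[1, 1]; w <- dims[2, 1]
  arr <- array(0, dim = c(length(pages), h, w))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]$data
  arr
}

#' Write a label movie to a multi-page TIFF
#'
#' Lossless integer round-trip: 16-bit unsigned pixels when all labels fit,
#' 32-bit otherwise, one page per frame, no compression.
#'
#' @param movie a [label_movie()].
#' @param path output file.
#' @export
write_label_movie <- function(movie, path) {
  stopifnot(inherits(movie, "label_movie"))
  mx <- max(movie$data)
  bits <- if (mx < 65536L) 16L else 32L
  pages <- lapply(seq_len(n_frames(movie)) - 1L,
                  function(t) frame_matrix(movie, t))
  write_tiff_pages(pages, path, bits = bits, sample_format = 1L)
}

read_float_movie <- function(path) {
  pages <- read_tiff_pages(path)
  pages_to_array(pages)
}

write_float_movie <- function(arr, path) {
  if (is.matrix(arr)) arr <- array(arr, dim = c(1L, dim(arr)))
  pages <- lapply(seq_len(dim(arr)[1]), function(t) {
    m <- arr[t, , , drop = TRUE]
    if (!is.matrix(m)) m <- matrix(m, dim(arr)[2], dim(arr)[3])
    m
  })
  write_tiff_pages(pages, path, bits = 32L, sample_format = 3L)
}

#' Read an event-probability movie
#'
#' Float TIFF with values in \[0, 1\] and the same `T x Y x X` geometry as
#' the label movie it will filter. A geometry mismatch is an error, never a
#' silent resample.
#'
#' @param path TIFF file of one event class.
#' @param geometry optional [label_movie()] (or `T x Y x X` dim vector) the
#'   probability movie must match.
#' @param tol tolerance on the \[0, 1\] range check.
#' @return a `T x Y x X` numeric array.
#' @export
read_probability_movie <- function(path, geometry = NULL, tol = 1e-6) {
  arr <- read_float_movie(path)
  if (min(arr) < -tol || max(arr) > 1 + tol)
    stop_data("probability movie outside [0,1]: range ",
              signif(min(arr), 4), " .. ", signif(max(arr), 4))
  arr[] <- pmin(pmax(arr, 0), 1)
  if (!is.null(geometry)) {
    want <- if (inherits(geometry, "label_movie")) dim(geometry$data)
            else as.integer(geometry)
    if (!identical(dim(arr), as.integer(want)))
      stop_data("probability movie geometry ",
                paste(dim(arr), collapse = "x"), " does not match labels ",
                paste(want, collapse = "x"))
  }
  arr
}

#' Write an event-probability movie (32-bit float TIFF)
#' @param arr numeric array `T x Y x X` in \[0, 1\].
#' @param path output file.
#' @export
write_probability_movie <- function(arr, path) {
  if (min(arr) < 0 || max(arr) > 1) stop_data("probabilities must be in [0,1]")
  write_float_movie(arr, path)
}

#' Read a raw-intensity movie (any numeric single-channel TIFF)
#' @param path TIFF file.
#' @return a `T x Y x X` numeric array.
#' @export
read_intensity_movie <- function(path) read_float_movie(path)

#' @rdname read_intensity_movie
#' @param arr numeric array `T x Y x X`.
#' @export
write_intensity_movie <- function(arr, path) write_float_movie(arr, path)

# -- track tables -------------------------------------------------------------

default_track_aliases <- function() list(
  track_id = c("track_id", "TRACK_ID", "TrackID", "track"),
  frame = c("frame", "FRAME", "POSITION_T", "t", "time"),
  label = c("label", "LABEL", "ID", "SPOT_ID"),
  y = c("y", "POSITION_Y", "centroid_y"),
  x = c("x", "POSITION_X", "centroid_x"),
  area = c("area", "AREA"),
  parent_track = c("parent_track", "PARENT_TRACK", "parent"))

#' Read a track table from CSV
#'
#' Requires at least track id, frame and label columns; third-party column
#' names are mapped through `aliases`. Rows come back sorted by
#' `(track_id, frame)`. `parent_track` uses the sentinel 0 for root tracks so
#' the column stays integer-typed. Duplicate `(frame, label)` pairs are an
#' integrity error that lists the offenders.
#'
#' @param path CSV file (comma-separated, header, '.' decimal).
#' @param aliases named list of accepted column names per canonical column.
#' @return a track data frame with columns `track_id`, `frame`, `label`,
#'   `y`, `x`, `area`, `parent_track` (and any extra columns found).
#' @export
read_track_csv <- function(path, aliases = default_track_aliases()) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  for (canon in names(aliases)) {
    if (canon %in% names(df)) next
    hit <- intersect(aliases[[canon]], names(df))
    if (length(hit)) names(df)[names(df) == hit[1]] <- canon
  }
  need <- c("track_id", "frame", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_data("track CSV missing required column(s): ",
              paste(miss, collapse = ", "))
  if (!"parent_track" %in% names(df)) df$parent_track <- 0L
  for (col in c("y", "x", "area")) if (!col %in% names(df)) df[[col]] <- NA_real_
  df$track_id <- as.integer(df$track_id)
  df$frame <- as.integer(df$frame)
  df$label <- as.integer(df$label)
  df$parent_track <- as.integer(df$parent_track)
  key <- paste(df$frame, df$label)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop_data("duplicate (frame,label) pairs in track CSV: ",
              paste(head(dup, 5), collapse = "; "),
              if (length(dup) > 5) " ..." else "")
  }
  if (any(df$parent_track == df$track_id))
    stop_data("track CSV has tracks that are their own parent")
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_track_csv
#' @param tracks a track data frame.
#' @export
write_track_csv <- function(tracks, path) {
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- event tables -------------------------------------------------------------

empty_event_list <- function() data.frame(
  event_id = integer(), kind = character(), frame = integer(),
  y = double(), x = double(), parent_track = integer(),
  daughter1 = integer(), daughter2 = integer())

check_event_list <- function(events) {
  bad <- events$kind == "division" &
    (is.na(events$daughter1) | is.na(events$daughter2))
  if (any(bad)) stop_data("division events must have exactly 2 daughters")
  bad <- events$kind == "extrusion" &
    (!is.na(events$daughter1) | !is.na(events$daughter2))
  if (any(bad)) stop_data("extrusion events must have no daughters")
  events
}

#' Read / write event tables (divisions, extrusions) as CSV
#' @param path CSV file.
#' @return a data frame with columns `event_id`, `kind`, `frame`, `y`, `x`,
#'   `parent_track`, `daughter1`, `daughter2` (daughters `NA` for
#'   extrusions).
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- read.csv(path)
  need <- c("event_id", "kind", "frame", "y", "x", "parent_track")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_data("events CSV missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("daughter1", "daughter2"))
    if (!col %in% names(df)) df[[col]] <- NA_integer_
  check_event_list(df)
}

#' @rdname read_events_csv
#' @param events an event data frame.
#' @export
write_events_csv <- function(events, path) {
  write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- edit scripts -------------------------------------------------------------

EDIT_OPS <- c("merge", "split", "draw_junction", "remove", "swap",
              "set_track", "fill")

#' Build an edit script
#'
#' An edit script is an ordered, replayable list of correction operations
#' (see [apply_edit_script()]). JSON is the canonical on-disk interchange
#' because seeded splits carry variable-length seed lists; flat operations
#' can also live in CSV.
#'
#' @param ... operations, each a named list with at least `op` and `frame`.
#' @return an object of class `edit_script`.
#' @export
edit_script <- function(...) {
  ops <- list(...)
  if (length(ops) == 1L && is.list(ops[[1]]) && is.null(ops[[1]]$op))
    ops <- ops[[1]]
  for (i in seq_along(ops)) check_edit_op(ops[[i]], i)
  structure(ops, class = "edit_script")
}

check_edit_op <- function(op, pos) {
  if (is.null(op$op) || !op$op %in% EDIT_OPS)
    stop_data("edit script op ", pos, ": unknown operation '",
              if (is.null(op$op)) "<missing>" else op$op, "'")
  if (is.null(op$frame)) stop_data("edit script op ", pos, ": missing frame")
  invisible(op)
}

#' @export
print.edit_script <- function(x, ...) {
  cat(sprintf("edit_script with %d operation(s)\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  %3d: %s @ frame %d\n", i, x[[i]]$op, x[[i]]$frame))
  invisible(x)
}

#' Read / write edit scripts
#'
#' JSON (canonical, any operation) or CSV (flat operations only: merge,
#' remove, swap, set_track). Unknown operation names are a parse error that
#' names the offending position.
#'
#' @param path `.json` or `.csv` file.
#' @return an `edit_script`.
#' @export
read_edit_script <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    ops <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    df <- read.csv(path)
    if (!nrow(df)) return(edit_script(list()))
    ops <- lapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, , drop = FALSE])
      row <- row[!vapply(row, function(v) is.na(v), logical(1))]
      row
    })
  }
  ops <- lapply(ops, function(op) {
    if (!is.null(op$seeds)) op$seeds <- do.call(rbind, lapply(op$seeds, unlist))
    if (!is.null(op$polyline)) op$polyline <- do.call(rbind, lapply(op$polyline, unlist))
    if (!is.null(op$seed)) op$seed <- unlist(op$seed)
    if (!is.null(op$part_labels)) op$part_labels <- unlist(op$part_labels)
    op
  })
  edit_script(ops)
}

#' @rdname read_edit_script
#' @param script an `edit_script`.
#' @export
write_edit_script <- function(script, path) {
  ops <- lapply(unclass(script), function(op) {
    if (!is.null(op$seeds)) op$seeds <- lapply(seq_len(nrow(op$seeds)),
                                               function(i) op$seeds[i, ])
    if (!is.null(op$polyline)) op$polyline <- lapply(seq_len(nrow(op$polyline)),
                                                     function(i) op$polyline[i, ])
    op
  })
  jsonlite::write_json(ops, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration file (JSON)
#'
#' A single structured file whose sections mirror the parameter objects:
#' `tracking` ([tracking_params()]), `flags` ([flag_config()]), `events`
#' ([event_params()]), `simulate` ([sim_params()]), `corrupt`
#' ([corruption_params()]), plus free-form `paths`.
#'
#' @param path JSON file.
#' @return a nested list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
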