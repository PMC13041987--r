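# Correction operators. Every operator edits the movie at one frame (or a
# frame range), keeps the track table consistent, and finishes by relinking
# the touched labels with their temporal neighbours (relink_after_edit), so
# a local fix propagates into the tracking without a global rebuild.

dilate8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- max(1, 1 + dy):min(h, h + dy)
    yt <- max(1, 1 - dy):min(h, h - dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    xt <- max(1, 1 - dx):min(w, w - dx)
    out[yt, xt] <- out[yt, xt] | mask[ys, xs]
  }
  out
}

fresh_label <- function(movie, n = 1L) max(movie$data) + seq_len(n)

# Junction-gap representation test, robust to stray background holes in a
# dense frame: in a true junction-gap frame essentially every cell borders
# the background skeleton.
frame_is_gap_rep <- function(m) {
  labs <- setdiff(unique(as.vector(m)), 0L)
  if (!length(labs) || !any(m == 0L)) return(FALSE)
  bgd <- dilate8(m == 0L)
  touching <- length(setdiff(unique(m[bgd]), 0L))
  touching > 0.5 * length(labs)
}

#' Merge two adjacent cells
#'
#' The union region keeps the lower of the two ids (deterministic and stable
#' under replay); junction-gap background pixels strictly between the two
#' regions are absorbed. The cell count of the frame drops by exactly one,
#' then the kept label is relinked with the neighbouring frames.
#'
#' @param movie,tracks the movie and its track table.
#' @param frame 0-based frame of the edit.
#' @param label_a,label_b labels to merge; they must be adjacent
#'   (see [neighbor_graph()]) — merging distant cells is a different intent.
#' @param relink run [relink_after_edit()] (default) on the result.
#' @param params [tracking_params()] used for relinking.
#' @return `list(movie, tracks, touched)`.
#' @export
merge_cells <- function(movie, tracks, frame, label_a, label_b,
                        relink = TRUE, params = tracking_params()) {
  if (label_a == label_b) stop_usage("cannot merge a label with itself")
  m <- frame_matrix(movie, frame)
  if (!any(m == label_a) || !any(m == label_b))
    stop_usage("labels ", label_a, ", ", label_b, " not both present at frame ",
               frame)
  adj <- cpp_adjacency(m, 2L)
  lo <- min(label_a, label_b); hi <- max(label_a, label_b)
  if (!any(adj$a == lo & adj$b == hi))
    stop_usage("labels ", label_a, " and ", label_b,
               " are not adjacent at frame ", frame)
  absorb <- if (frame_is_gap_rep(m))
    m == 0L & dilate8(m == label_a) & dilate8(m == label_b)
  else matrix(FALSE, nrow(m), ncol(m))
  m[m == hi | absorb] <- lo
  movie <- set_frame_matrix(movie, frame, m)
  tracks <- tracks[!(tracks$frame == frame & tracks$label == hi), ,
                   drop = FALSE]
  if (relink) tracks <- relink_after_edit(movie, tracks, frame, lo, params)
  list(movie = movie, tracks = tracks, touched = lo)
}

#' Split a cell from seed points
#'
#' Partitions the region by marker-controlled watershed restricted to the
#' region. The relief is the raw intensity when supplied (junction-bright
#' markers flood naturally), otherwise the inverted distance transform of
#' the region (`relief = "distance"`). `relief = "nearest_seed"` assigns
#' each pixel to its nearest seed instead — the exact inverse of merging two
#' equal-weight tessellation cells, used by corruption-inverse scripts.
#'
#' @inheritParams merge_cells
#' @param label the cell to split.
#' @param seeds numeric `k x 2` matrix of (y, x) seed coordinates (0-based),
#'   `k >= 2`, all inside the region.
#' @param intensity optional raw-intensity frame (`Y x X` matrix) used as
#'   relief.
#' @param relief `"distance"` (default) or `"nearest_seed"`.
#' @param part_labels optional integer vector of length `k`: the label each
#'   seed's part receives (must contain `label` once; others must be unused
#'   in the frame). Default: seed 1 keeps `label`, the rest get fresh ids.
#' @return `list(movie, tracks, touched, part_labels)`.
#' @export
split_cell <- function(movie, tracks, frame, label, seeds, intensity = NULL,
                       relief = c("distance", "nearest_seed"),
                       part_labels = NULL, relink = TRUE,
                       params = tracking_params()) {
  relief <- match.arg(relief)
  seeds <- matrix(as.numeric(seeds), ncol = 2)
  if (nrow(seeds) < 2) stop_usage("split needs at least 2 seeds")
  m <- frame_matrix(movie, frame)
  mask <- m == label
  if (!any(mask)) stop_usage("label ", label, " absent at frame ", frame)
  si <- round(seeds) + 1L   # to 1-based matrix indices
  inside <- si[, 1] >= 1 & si[, 1] <= nrow(m) & si[, 2] >= 1 &
    si[, 2] <= ncol(m)
  if (!all(inside) || !all(mask[si[inside, , drop = FALSE]]))
    stop_usage("all seeds must lie inside the region of label ", label)
  k <- nrow(seeds)
  if (relief == "nearest_seed") {
    parts <- cpp_nearest_seed(mask, seeds[, 1], seeds[, 2])
  } else {
    rel <- if (!is.null(intensity)) intensity else -cpp_edt(mask)
    markers <- matrix(0L, nrow(m), ncol(m))
    markers[si] <- seq_len(k)
    parts <- cpp_watershed(rel, markers, mask)
  }
  sizes <- tabulate(parts[parts > 0], nbins = k)
  if (any(sizes == 0)) stop_usage("degenerate split: a seed produced no part")
  if (is.null(part_labels)) {
    part_labels <- c(label, fresh_label(movie, k - 1L))
  } else {
    part_labels <- as.integer(part_labels)
    if (length(part_labels) != k || sum(part_labels == label) != 1L)
      stop_usage("part_labels must give one label per seed, one of them '",
                 label, "'")
    clash <- setdiff(part_labels, label)
    if (any(clash %in% m))
      stop_usage("part_labels already present at frame ", frame, ": ",
                 paste(intersect(clash, m), collapse = ", "))
  }
  for (p in seq_len(k)) m[parts == p] <- part_labels[p]
  comp <- cpp_components4(m)
  for (p in part_labels) {
    if (length(unique(comp[m == p])) != 1L)
      stop_usage("split produced a disconnected part for label ", p)
  }
  movie <- set_frame_matrix(movie, frame, m)
  if (relink) tracks <- relink_after_edit(movie, tracks, frame, part_labels,
                                          params)
  list(movie = movie, tracks = tracks, touched = part_labels,
       part_labels = part_labels)
}

bresenham <- function(y0, x0, y1, x1) {
  # integer line rasterisation, endpoints included, 0-based
  dy <- abs(y1 - y0); dx <- abs(x1 - x0)
  sy <- sign(y1 - y0); sx <- sign(x1 - x0)
  err <- dx - dy
  y <- y0; x <- x0
  pts <- list()
  repeat {
    pts[[length(pts) + 1L]] <- c(y, x)
    if (y == y1 && x == x1) break
    e2 <- 2 * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dy; y <- y + sy }
  }
  do.call(rbind, pts)
}

rasterize_polyline <- function(polyline) {
  polyline <- round(matrix(as.numeric(polyline), ncol = 2))
  pts <- NULL
  for (k in seq_len(nrow(polyline) - 1L))
    pts <- rbind(pts, bresenham(polyline[k, 1], polyline[k, 2],
                                polyline[k + 1, 1], polyline[k + 1, 2]))
  pts[!duplicated(pts), , drop = FALSE]
}

#' Split a cell by drawing a junction
#'
#' Rasterises the polyline (Bresenham per segment) and splits the single
#' crossed cell along it into exactly two labels, preserving confluence: in
#' junction-gap movies the path becomes background skeleton, in dense movies
#' each path pixel joins the side it shares most edges with. The endpoints
#' may lie on the existing junction network, the border, or neighbouring
#' cells; the interior of the path must stay within one cell.
#'
#' @inheritParams merge_cells
#' @param polyline numeric `n x 2` matrix of (y, x) vertices (0-based).
#' @return `list(movie, tracks, touched, new_label)`.
#' @export
draw_junction <- function(movie, tracks, frame, polyline, relink = TRUE,
                          params = tracking_params()) {
  m <- frame_matrix(movie, frame)
  h <- nrow(m); w <- ncol(m)
  pts <- rasterize_polyline(polyline)
  if (any(pts[, 1] < 0 | pts[, 1] >= h | pts[, 2] < 0 | pts[, 2] >= w))
    stop_usage("polyline leaves the image")
  idx <- pts[, 1] + 1L + pts[, 2] * h
  inner <- idx
  if (length(idx) > 2) inner <- idx[-c(1, length(idx))]
  labs <- unique(m[inner])
  labs <- setdiff(labs, 0L)
  if (length(labs) != 1L)
    stop_usage("junction path must cross exactly one cell, found ",
               length(labs))
  L <- labs
  path_in <- idx[m[idx] == L]
  mask <- m == L
  mask[path_in] <- FALSE
  comp <- cpp_components4(matrix(as.integer(mask), h, w))
  ncomp <- max(comp)
  if (ncomp != 2L)
    stop_usage("junction path does not separate the cell into two parts (",
               ncomp, " part(s))")
  sizes <- tabulate(comp[comp > 0], nbins = 2L)
  keep_comp <- which.max(sizes)           # larger part keeps the label
  newL <- fresh_label(movie)
  m[mask] <- ifelse(comp[mask] == keep_comp, L, newL)
  gap_rep <- frame_is_gap_rep(frame_matrix(movie, frame))
  if (gap_rep) {
    m[path_in] <- 0L
  } else {
    # assign each path pixel to the side it touches most (4-neighbourhood)
    for (p in path_in) {
      y <- (p - 1L) %% h + 1L; x <- (p - 1L) %/% h + 1L
      nb <- c(if (y > 1) m[y - 1, x], if (y < h) m[y + 1, x],
              if (x > 1) m[y, x - 1], if (x < w) m[y, x + 1])
      nL <- sum(nb == L); nN <- sum(nb == newL)
      m[p] <- if (nN > nL) newL else L
    }
  }
  movie <- set_frame_matrix(movie, frame, m)
  if (relink) tracks <- relink_after_edit(movie, tracks, frame, c(L, newL),
                                          params)
  list(movie = movie, tracks = tracks, touched = c(L, newL), new_label = newL)
}

#' Remove a track's cell from a frame onward
#'
#' The track's pixels from `frame_from` to its end become background, or are
#' absorbed by the neighbour sharing the longest boundary when
#' `repair = TRUE` (confluence repair). The track table is truncated.
#'
#' @inheritParams merge_cells
#' @param frame_from first frame to clear (0-based).
#' @param track_id the track to remove.
#' @param repair assign vacated pixels to the dominant neighbour instead of
#'   background.
#' @return `list(movie, tracks)`.
#' @export
remove_cell <- function(movie, tracks, frame_from, track_id, repair = FALSE) {
  rows <- tracks[tracks$track_id == track_id & tracks$frame >= frame_from, ,
                 drop = FALSE]
  if (!any(tracks$track_id == track_id))
    stop_usage("unknown track ", track_id)
  if (!nrow(rows))
    stop_usage("track ", track_id, " has no observations at frame >= ",
               frame_from)
  for (k in seq_len(nrow(rows))) {
    fr <- rows$frame[k]; lab <- rows$label[k]
    m <- frame_matrix(movie, fr)
    if (repair) {
      adj <- cpp_adjacency(m, 2L)
      nb <- adj[adj$a == lab | adj$b == lab, , drop = FALSE]
      if (nrow(nb)) {
        best <- nb[which.max(nb$contact), ]
        target <- if (best$a == lab) best$b else best$a
        m[m == lab] <- target
      } else m[m == lab] <- 0L
    } else {
      m[m == lab] <- 0L
    }
    movie <- set_frame_matrix(movie, fr, m)
  }
  tracks <- tracks[!(tracks$track_id == track_id &
                       tracks$frame >= frame_from), , drop = FALSE]
  list(movie = movie, tracks = tracks)
}

# TRUE when the table uses the label-equals-track-id convention, in which
# case identity edits must also remap movie pixels.
labels_are_tracks <- function(tracks) all(tracks$label == tracks$track_id)

#' Exchange two track identities from a frame onward
#'
#' Swaps the track assignment of the two cells from `frame_from` to each
#' track's end (an involution: applying it twice is the identity). When the
#' table uses the label-equals-track-id convention, movie pixels are
#' remapped accordingly.
#'
#' @inheritParams remove_cell
#' @param track_a,track_b tracks to exchange.
#' @return `list(movie, tracks)`.
#' @export
swap_tracks <- function(movie, tracks, frame_from, track_a, track_b) {
  if (!all(c(track_a, track_b) %in% tracks$track_id))
    stop_usage("unknown track id(s): ",
               paste(setdiff(c(track_a, track_b), tracks$track_id),
                     collapse = ", "))
  if (track_a == track_b) return(list(movie = movie, tracks = tracks))
  sel_a <- tracks$track_id == track_a & tracks$frame >= frame_from
  sel_b <- tracks$track_id == track_b & tracks$frame >= frame_from
  remap_movie <- labels_are_tracks(tracks)
  if (remap_movie) {
    frames <- sort(unique(tracks$frame[sel_a | sel_b]))
    for (fr in frames) {
      m <- frame_matrix(movie, fr)
      ia <- m == track_a; ib <- m == track_b
      m[ia] <- track_b; m[ib] <- track_a
      movie <- set_frame_matrix(movie, fr, m)
    }
    tracks$label[sel_a] <- track_b
    tracks$label[sel_b] <- track_a
  }
  tracks$track_id[sel_a] <- track_b
  tracks$track_id[sel_b] <- track_a
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  list(movie = movie, tracks = tracks)
}

#' Reassign a track id from a frame onward
#'
#' Moves the observations of `from_track` at `frame_from` and later into
#' `to_track` (manual track join). Errors if `to_track` already has
#' observations in those frames.
#'
#' @inheritParams remove_cell
#' @param from_track,to_track source and destination track ids.
#' @return `list(movie, tracks)`.
#' @export
set_track <- function(movie, tracks, frame_from, from_track, to_track) {
  sel <- tracks$track_id == from_track & tracks$frame >= frame_from
  if (!any(sel)) stop_usage("track ", from_track, " has no rows at frame >= ",
                            frame_from)
  clash <- tracks$track_id == to_track & tracks$frame %in% tracks$frame[sel]
  if (any(clash))
    stop_usage("track ", to_track, " already observed in the target frames")
  remap_movie <- labels_are_tracks(tracks)
  if (remap_movie) {
    for (k in which(sel)) {
      fr <- tracks$frame[k]
      m <- frame_matrix(movie, fr)
      m[m == tracks$label[k]] <- to_track
      movie <- set_frame_matrix(movie, fr, m)
    }
    tracks$label[sel] <- to_track
  }
  tracks$track_id[sel] <- to_track
  list(movie = movie, tracks = tracks)
}

#' Fill a background hole with a cell
#'
#' Assigns the 4-connected background component containing `seed` to a
#' label (fresh by default): the seed-based local correction for a cell
#' missing from a single frame of a confluent movie.
#'
#' @inheritParams merge_cells
#' @param seed (y, x) position inside the hole (0-based).
#' @param label label for the restored cell; default a fresh unused id. Must
#'   not already be present in the frame.
#' @return `list(movie, tracks, touched)`.
#' @export
fill_hole <- function(movie, tracks, frame, seed, label = NULL,
                      relink = TRUE, params = tracking_params()) {
  m <- frame_matrix(movie, frame)
  sy <- round(seed[1]) + 1L; sx <- round(seed[2]) + 1L
  if (sy < 1 || sy > nrow(m) || sx < 1 || sx > ncol(m) || m[sy, sx] != 0L)
    stop_usage("seed (", seed[1], ",", seed[2],
               ") is not on background at frame ", frame)
  if (is.null(label)) label <- fresh_label(movie)
  if (any(m == label))
    stop_usage("label ", label, " already present at frame ", frame)
  bg <- matrix(as.integer(m == 0L), nrow(m), ncol(m))
  comp <- cpp_components4(bg)
  m[comp == comp[sy, sx]] <- as.integer(label)
  movie <- set_frame_matrix(movie, frame, m)
  if (relink) tracks <- relink_after_edit(movie, tracks, frame, label, params)
  list(movie = movie, tracks = tracks, touched = label)
}

#' Replay an edit script
#'
#' Applies the operations in order. On a failing operation the replay stops:
#' operations before it remain applied and the failure position is reported
#' (as a classed error by default, or in the returned log when
#' `stop_on_error = FALSE`).
#'
#' @inheritParams merge_cells
#' @param script an [edit_script()].
#' @param stop_on_error throw on the first failing op (default) or return
#'   the partial result.
#' @return `list(movie, tracks, log, failed_at, error)`; `failed_at` is `NA`
#'   on full success.
#' @export
apply_edit_script <- function(movie, tracks, script,
                              params = tracking_params(),
                              stop_on_error = TRUE) {
  log <- NULL
  failed_at <- NA_integer_; err_msg <- NA_character_
  for (k in seq_along(script)) {
    op <- script[[k]]
    res <- tryCatch({
      switch(op$op,
        merge = merge_cells(movie, tracks, op$frame, op$label_a, op$label_b,
                            params = params),
        split = split_cell(movie, tracks, op$frame, op$label, op$seeds,
                           relief = if (is.null(op$relief)) "distance"
                                    else op$relief,
                           part_labels = op$part_labels, params = params),
        draw_junction = draw_junction(movie, tracks, op$frame, op$polyline,
                                      params = params),
        remove = remove_cell(movie, tracks, op$frame, op$track_id,
                             repair = isTRUE(op$repair)),
        swap = swap_tracks(movie, tracks, op$frame, op$track_a, op$track_b),
        set_track = set_track(movie, tracks, op$frame, op$from_track,
                              op$to_track),
        fill = fill_hole(movie, tracks, op$frame, op$seed, op$label,
                         params = params),
        stop_usage("unknown operation '", op$op, "'"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed_at <- k
      err_msg <- conditionMessage(res)
      log <- rbind(log, data.frame(position = k, op = op$op, frame = op$frame,
                                   status = "error"))
      if (stop_on_error)
        stop(errorCondition(
          sprintf("edit script failed at operation %d (%s): %s", k, op$op,
                  err_msg),
          class = c("tc_script_error", "tc_data_error", "error"),
          position = k))
      break
    }
    movie <- res$movie; tracks <- res$tracks
    log <- rbind(log, data.frame(position = k, op = op$op, frame = op$frame,
                                 status = "ok"))
  }
  if (is.null(log))
    log <- data.frame(position = integer(), op = character(),
                      frame = integer(), status = character())
  list(movie = movie, tracks = tracks, log = log, failed_at = failed_at,
       error = err_msg)
}
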