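#' Event-detection parameters
#'
#' @param div_radius radius (px) around a disappearing track's last centroid
#'   within which daughter starts are sought; `NULL` = twice the median cell
#'   diameter of the frame (scale-free default).
#' @param division_area_frac a daughter must be at most this fraction of the
#'   parent's final area (a true daughter is about half); prevents tracks
#'   that end tiny — extrusions — from being claimed as division parents by
#'   unrelated nearby track starts.
#' @param extrusion_area_max maximal final area of an extruding track:
#'   values `<= 1` are a fraction of the frame's median cell area (default
#'   0.25), larger values are absolute pixels.
#' @param prob_threshold probability above which an external event detector
#'   confirms an event (default 0.5).
#' @param prob_window_px,prob_window_frames half-size of the spatiotemporal
#'   window, in pixels and frames, over which the probability movie is
#'   maximised around an event (defaults 10 px, 2 frames).
#' @param border_margin pixels from the border within which a track end is
#'   treated as leaving the field of view.
#' @return a list of class `event_params`.
#' @export
event_params <- function(div_radius = NULL, division_area_frac = 0.7,
                         extrusion_area_max = 0.25,
                         prob_threshold = 0.5, prob_window_px = 10,
                         prob_window_frames = 2, border_margin = 2) {
  stopifnot(is.null(div_radius) || div_radius > 0, extrusion_area_max > 0,
            prob_threshold >= 0, prob_threshold <= 1)
  structure(list(div_radius = div_radius,
                 division_area_frac = division_area_frac,
                 extrusion_area_max = extrusion_area_max,
                 prob_threshold = prob_threshold,
                 prob_window_px = prob_window_px,
                 prob_window_frames = prob_window_frames,
                 border_margin = border_margin),
            class = "event_params")
}

#' Detect divisions from track topology
#'
#' A division is scored whenever one track disappears and at least two
#' tracks appear very nearby at the next frame: the two nearest starters
#' become the daughters, each starter is consumed by at most one division,
#' and the event is placed in the middle of the two daughter cells at the
#' first frame of their appearance.
#'
#' @param tracks a track table.
#' @param params an [event_params()].
#' @return an event table (columns as [read_events_csv()]).
#' @export
detect_divisions <- function(tracks, params = event_params()) {
  ext <- track_extents(tracks)
  Tlast <- max(tracks$frame)
  first_row <- tracks[match(paste(ext$track_id, ext$start),
                            paste(tracks$track_id, tracks$frame)), ]
  last_row <- tracks[match(paste(ext$track_id, ext$end),
                           paste(tracks$track_id, tracks$frame)), ]
  events <- empty_event_list()
  consumed_start <- logical(nrow(ext))
  ends <- which(ext$end < Tlast)
  ends <- ends[order(ext$end[ends], ext$track_id[ends])]
  for (e in ends) {
    t_end <- ext$end[e]
    starters <- which(ext$start == t_end + 1L & !consumed_start)
    if (length(starters) < 2L) next
    d <- sqrt((first_row$y[starters] - last_row$y[e])^2 +
                (first_row$x[starters] - last_row$x[e])^2)
    r_div <- params$div_radius
    if (is.null(r_div)) {
      areas <- tracks$area[tracks$frame == t_end]
      r_div <- auto_division_radius(areas)
    }
    near <- starters[d <= r_div]
    if (!is.na(last_row$area[e]) && !is.null(params$division_area_frac))
      near <- near[is.na(first_row$area[near]) |
                     first_row$area[near] <=
                       params$division_area_frac * last_row$area[e]]
    if (length(near) < 2L) next
    ord <- order(d[match(near, starters)], ext$track_id[near])
    dgt <- near[ord[1:2]]
    consumed_start[dgt] <- TRUE
    events <- rbind(events, data.frame(
      event_id = nrow(events) + 1L, kind = "division", frame = t_end + 1L,
      y = mean(first_row$y[dgt]), x = mean(first_row$x[dgt]),
      parent_track = ext$track_id[e],
      daughter1 = min(ext$track_id[dgt]), daughter2 = max(ext$track_id[dgt])))
  }
  events
}

#' Detect extrusions from track topology
#'
#' A track ending before the last frame, that is not a division parent, does
#' not leave at the border, and whose final apical area has shrunk below the
#' extrusion threshold is marked as an extrusion, placed at its centroid in
#' the last frame where the cell area is still visible.
#'
#' @param tracks a track table.
#' @param divisions the division events already detected.
#' @param params an [event_params()].
#' @param dims optional `c(T, Y, X)` geometry (taken from
#'   `attr(tracks, "dims")` when present) for the border test.
#' @return an event table.
#' @export
detect_extrusions <- function(tracks, divisions = empty_event_list(),
                              params = event_params(),
                              dims = attr(tracks, "dims")) {
  ext <- track_extents(tracks)
  Tlast <- max(tracks$frame)
  events <- empty_event_list()
  for (e in seq_len(nrow(ext))) {
    if (ext$end[e] >= Tlast) next
    tid <- ext$track_id[e]
    if (tid %in% divisions$parent_track) next
    lr <- tracks[tracks$track_id == tid & tracks$frame == ext$end[e], ]
    if (!is.null(dims)) {
      if (row_near_border(lr, dims[2], dims[3], params$border_margin)) next
    }
    if (is.na(lr$area)) next
    amax <- params$extrusion_area_max
    if (amax <= 1) {
      med <- median(tracks$area[tracks$frame == ext$end[e]], na.rm = TRUE)
      amax <- amax * med
    }
    if (lr$area > amax) next
    events <- rbind(events, data.frame(
      event_id = nrow(events) + 1L, kind = "extrusion", frame = ext$end[e],
      y = lr$y, x = lr$x, parent_track = tid,
      daughter1 = NA_integer_, daughter2 = NA_integer_))
  }
  events$event_id <- seq_len(nrow(events)) + 0L
  events
}

#' Cross-filter events with an external probability movie
#'
#' Keeps an event iff the probability movie exceeds `prob_threshold`
#' somewhere in the spatiotemporal window (`prob_window_px` pixels,
#' `prob_window_frames` frames) around it. Order preserving; monotone in
#' the threshold.
#'
#' @param events an event table.
#' @param prob_movie `T x Y x X` probability array (see
#'   [read_probability_movie()]).
#' @param params an [event_params()].
#' @return the filtered event table.
#' @export
filter_events_by_probability <- function(events, prob_movie,
                                         params = event_params()) {
  d <- dim(prob_movie)
  keep <- vapply(seq_len(nrow(events)), function(k) {
    fr <- events$frame[k]
    if (fr < 0 || fr > d[1] - 1)
      stop_data("event frame ", fr, " outside probability movie geometry")
    t0 <- max(0, fr - params$prob_window_frames)
    t1 <- min(d[1] - 1, fr + params$prob_window_frames)
    y0 <- max(0, floor(events$y[k] - params$prob_window_px))
    y1 <- min(d[2] - 1, ceiling(events$y[k] + params$prob_window_px))
    x0 <- max(0, floor(events$x[k] - params$prob_window_px))
    x1 <- min(d[3] - 1, ceiling(events$x[k] + params$prob_window_px))
    max(prob_movie[(t0:t1) + 1, (y0:y1) + 1, (x0:x1) + 1]) >=
      params$prob_threshold
  }, logical(1))
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify tracks by fate
#'
#' Marks every division parent as `"Dividing"` and every extruding track as
#' `"Extruding"` (terminal-track semantics). A track in both is an
#' integrity error: a cell cannot divide and extrude at the same terminal.
#'
#' @param tracks a track table.
#' @param events an event table.
#' @return a data frame `track_id`, `group` for all tracks (`"none"` when
#'   no fate applies).
#' @export
fate_groups <- function(tracks, events) {
  ids <- sort(unique(tracks$track_id))
  div <- unique(events$parent_track[events$kind == "division"])
  ext <- unique(events$parent_track[events$kind == "extrusion"])
  both <- intersect(div, ext)
  if (length(both))
    stop_data("track(s) marked both Dividing and Extruding: ",
              paste(both, collapse = ", "))
  grp <- rep("none", length(ids))
  grp[ids %in% div] <- "Dividing"
  grp[ids %in% ext] <- "Extruding"
  data.frame(track_id = ids, group = grp)
}

#' Relative apical area until an event
#'
#' For each event's terminal track, the ratio of the cell's area to the mean
#' area of its neighbours at every frame from the track's start up to the
#' event, time-aligned so that the event is `t_rel = 0` (negative before).
#' Frames where the cell has no neighbours yield `NA`.
#'
#' @param events an event table.
#' @param features a cell-feature table ([cell_features()]) carrying
#'   `frame`, `label`, `track_id`, `area` and the `neighbors` list column.
#' @return a long data frame `event_id`, `kind`, `track_id`, `frame`,
#'   `t_rel`, `ratio`.
#' @export
relative_area_to_event <- function(events, features) {
  if (!"neighbors" %in% names(features))
    stop_usage("features table must carry the 'neighbors' list column")
  out <- list()
  for (k in seq_len(nrow(events))) {
    tid <- events$parent_track[k]
    rows <- features[features$track_id == tid &
                       features$frame <= events$frame[k], , drop = FALSE]
    rows <- rows[order(rows$frame), , drop = FALSE]
    if (!nrow(rows)) next
    ratio <- vapply(seq_len(nrow(rows)), function(i) {
      nb <- rows$neighbors[[i]]
      if (!length(nb)) return(NA_real_)
      nb_rows <- features[features$frame == rows$frame[i] &
                            features$label %in% nb, , drop = FALSE]
      if (!nrow(nb_rows)) return(NA_real_)
      rows$area[i] / mean(nb_rows$area)
    }, double(1))
    out[[k]] <- data.frame(event_id = events$event_id[k],
                           kind = events$kind[k], track_id = tid,
                           frame = rows$frame,
                           t_rel = rows$frame - events$frame[k],
                           ratio = ratio)
  }
  if (!length(out))
    return(data.frame(event_id = integer(), kind = character(),
                      track_id = integer(), frame = integer(),
                      t_rel = integer(), ratio = double()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
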