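#' Configuration of suspicious-track flags
#'
#' Which track anomalies to flag for curation. The taxonomy covers the two
#' classic suspicion categories — unexpected appearance/disappearance and
#' sudden change of a cell property — plus short tracks, internal gaps and
#' positional jumps (a sudden change of position, the signature of a track
#' identity swap). Border tracks are exempt from appearance/disappearance
#' flags because cells legitimately enter and leave the field of view.
#'
#' @param flag_appear flag tracks starting after frame 0 away from the
#'   border and not registered as division daughters.
#' @param flag_disappear flag tracks ending before the last frame away from
#'   the border and not registered as division parents or extrusions.
#' @param flag_area_jump flag consecutive-frame area ratios above
#'   `area_jump_ratio`.
#' @param area_jump_ratio ratio `max(A_t, A_t+1)/min(A_t, A_t+1)` above
#'   which an area change is suspicious (default 1.5, so an honest division
#'   halving is flagged only when not registered as a division).
#' @param area_jump_min_frac an area change must additionally exceed this
#'   fraction of the median cell area to be flagged: pure ratios over-fire
#'   on small cells where a few pixels of honest boundary motion are a
#'   large relative change.
#' @param flag_short_track flag tracks shorter than `min_track_len` frames.
#' @param min_track_len minimal unsuspicious track duration (frames).
#' @param flag_gap flag frames missing inside a track's extent.
#' @param flag_position_jump flag centroid displacements above
#'   `max_jump_distance` between consecutive frames.
#' @param max_jump_distance displacement threshold in pixels.
#' @param border_margin pixels from the image border within which a track
#'   end is considered "at the border".
#' @return a list of class `flag_config`.
#' @export
flag_config <- function(flag_appear = TRUE, flag_disappear = TRUE,
                        flag_area_jump = TRUE, area_jump_ratio = 1.5,
                        area_jump_min_frac = 0.1,
                        flag_short_track = TRUE, min_track_len = 2,
                        flag_gap = TRUE, flag_position_jump = TRUE,
                        max_jump_distance = 10, border_margin = 2) {
  stopifnot(area_jump_ratio > 1, min_track_len >= 1, border_margin >= 0)
  structure(list(flag_appear = flag_appear, flag_disappear = flag_disappear,
                 flag_area_jump = flag_area_jump,
                 area_jump_ratio = area_jump_ratio,
                 area_jump_min_frac = area_jump_min_frac,
                 flag_short_track = flag_short_track,
                 min_track_len = min_track_len, flag_gap = flag_gap,
                 flag_position_jump = flag_position_jump,
                 max_jump_distance = max_jump_distance,
                 border_margin = border_margin),
            class = "flag_config")
}

row_near_border <- function(rows, h, w, margin) {
  if (all(c("ymin", "xmin", "ymax", "xmax") %in% names(rows)) &&
      !anyNA(rows$ymin)) {
    rows$ymin <= margin | rows$xmin <= margin |
      rows$ymax >= h - 1 - margin | rows$xmax >= w - 1 - margin
  } else if ("touches_border" %in% names(rows) && !anyNA(rows$touches_border)) {
    rows$touches_border
  } else {
    rows$y <= 3 * margin | rows$x <= 3 * margin |
      rows$y >= h - 1 - 3 * margin | rows$x >= w - 1 - 3 * margin
  }
}

#' Flag suspicious tracks
#'
#' Scans a track table for the anomalies enabled in `cfg` (see
#' [flag_config()]). Tracks registered in `events` are exempt from the flags
#' their event explains: division daughters from appearance, division
#' parents and extrusions from disappearance.
#'
#' @param movie the [label_movie()] the tracks describe (for geometry).
#' @param tracks a track table.
#' @param events optional event table ([detect_divisions()] /
#'   [detect_extrusions()] or ground truth) of registered events.
#' @param cfg a [flag_config()].
#' @return a data frame `track_id`, `frame`, `kind`, `detail`, sorted by
#'   (frame, track_id).
#' @export
flag_suspicious <- function(movie, tracks, events = NULL, cfg = flag_config()) {
  d <- dim(movie$data); Tn <- d[1]; h <- d[2]; w <- d[3]
  daughters <- parents <- extruders <- integer(0)
  if (!is.null(events) && nrow(events)) {
    div <- events[events$kind == "division", ]
    daughters <- c(div$daughter1, div$daughter2)
    parents <- div$parent_track
    extruders <- events$parent_track[events$kind == "extrusion"]
  }
  med_area <- if (all(is.na(tracks$area))) 0
              else median(tracks$area, na.rm = TRUE)
  out <- list()
  add <- function(tid, fr, kind, detail)
    out[[length(out) + 1L]] <<- data.frame(track_id = tid, frame = fr,
                                           kind = kind, detail = detail)
  for (tid in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == tid, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    nb <- row_near_border(tr, h, w, cfg$border_margin)
    if (cfg$flag_appear && tr$frame[1] > 0 && !nb[1] &&
        !tid %in% daughters)
      add(tid, tr$frame[1], "appear",
          sprintf("track starts at frame %d in the tissue interior",
                  tr$frame[1]))
    last <- nrow(tr)
    if (cfg$flag_disappear && tr$frame[last] < Tn - 1 && !nb[last] &&
        !tid %in% parents && !tid %in% extruders)
      add(tid, tr$frame[last], "disappear",
          sprintf("track ends at frame %d in the tissue interior",
                  tr$frame[last]))
    if (cfg$flag_short_track && last < cfg$min_track_len)
      add(tid, tr$frame[1], "short_track",
          sprintf("track lasts %d frame(s)", last))
    if (cfg$flag_gap && last > 1) {
      dfr <- diff(tr$frame)
      for (k in which(dfr > 1))
        add(tid, tr$frame[k] + 1L, "gap",
            sprintf("no observation for %d frame(s) after frame %d",
                    dfr[k] - 1L, tr$frame[k]))
    }
    if (last > 1) {
      consec <- which(diff(tr$frame) == 1L)
      if (cfg$flag_area_jump && !anyNA(tr$area) && !tid %in% extruders) {
        a1 <- tr$area[consec]; a2 <- tr$area[consec + 1L]
        jump <- pmax(a1, a2) / pmin(a1, a2) > cfg$area_jump_ratio &
          abs(a2 - a1) >= cfg$area_jump_min_frac * med_area
        for (k in consec[jump])
          add(tid, tr$frame[k + 1L], "area_jump",
              sprintf("area %d -> %d between frames %d and %d",
                      tr$area[k], tr$area[k + 1L], tr$frame[k],
                      tr$frame[k + 1L]))
      }
      if (cfg$flag_position_jump && !anyNA(tr$y)) {
        dd <- sqrt((tr$y[consec + 1L] - tr$y[consec])^2 +
                     (tr$x[consec + 1L] - tr$x[consec])^2)
        for (k in consec[dd > cfg$max_jump_distance])
          add(tid, tr$frame[k + 1L], "position_jump",
              sprintf("centroid moved %.1f px between frames %d and %d",
                      sqrt((tr$y[k + 1L] - tr$y[k])^2 +
                             (tr$x[k + 1L] - tr$x[k])^2),
                      tr$frame[k], tr$frame[k + 1L]))
      }
    }
  }
  if (!length(out))
    return(data.frame(track_id = integer(), frame = integer(),
                      kind = character(), detail = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$frame, res$track_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
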