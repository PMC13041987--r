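#' Tracking parameters
#'
#' Frame-to-frame linking minimises, over one-to-one matchings, the cost
#' `d^2 * (1 + w_A * |A_i - A_j| / max(A_i, A_j))` where `d` is the centroid
#' distance and `A` the area: quadratic distance is the standard
#' linear-assignment practice, and the relative-area penalty implements the
#' "link only cells of similar area" constraint in a scale-free way. Links
#' beyond `max_link_distance` are forbidden; every region can instead stay
#' unlinked at the fixed alternative cost `max_link_distance^2`.
#'
#' @param max_link_distance maximum centroid displacement per frame (px).
#' @param area_weight weight `w_A` of the relative-area penalty (unitless).
#' @param max_gap_frames maximum number of missed frames a track may bridge.
#' @param division_search_radius radius within which daughter candidates are
#'   sought around a disappearing track (px); `NULL` = twice the median cell
#'   diameter of the frame.
#' @param division_area_frac a daughter candidate must be at most this
#'   fraction of the parent's area (a true daughter is about half).
#' @param overlap_min minimal pixel-overlap fraction (of the smaller region)
#'   for a corrected cell to inherit a track during relinking.
#' @return a list of class `tracking_params`.
#' @export
tracking_params <- function(max_link_distance = 10, area_weight = 1,
                            max_gap_frames = 1, division_search_radius = NULL,
                            division_area_frac = 0.7, overlap_min = 0.5) {
  stopifnot(max_link_distance > 0, area_weight >= 0, max_gap_frames >= 0,
            is.null(division_search_radius) || division_search_radius > 0,
            overlap_min > 0, overlap_min <= 1)
  structure(list(max_link_distance = max_link_distance,
                 area_weight = area_weight, max_gap_frames = max_gap_frames,
                 division_search_radius = division_search_radius,
                 division_area_frac = division_area_frac,
                 overlap_min = overlap_min),
            class = "tracking_params")
}

link_cost_matrix <- function(ra, rb, params) {
  n <- nrow(ra); m <- nrow(rb)
  dy <- outer(ra$y, rb$y, "-"); dx <- outer(ra$x, rb$x, "-")
  d2 <- dy * dy + dx * dx
  amax <- outer(ra$area, rb$area, pmax)
  adiff <- abs(outer(ra$area, rb$area, "-"))
  cost <- d2 * (1 + params$area_weight * adiff / amax)
  cost[d2 > params$max_link_distance^2] <- Inf
  cost
}

#' Link the cells of two consecutive frames
#'
#' Solves the rectangular assignment with per-region no-link alternatives
#' priced at `max_link_distance^2` (the classic augmented-matrix
#' construction), so the returned matching minimises total link cost plus
#' the no-link charges. Deterministic: regions are processed in label order
#' and the solver is order-stable among equal-cost optima.
#'
#' @param regions_t,regions_t1 region tables ([region_table()]) of frames
#'   `t` and `t+1`.
#' @param params a [tracking_params()].
#' @return a list with `matches` (data frame `i`, `j`, row indices into the
#'   two tables, plus `cost`), `unmatched_t`, `unmatched_t1` (row indices),
#'   and `total_cost` (matched costs + no-link charges).
#' @export
link_frames <- function(regions_t, regions_t1, params = tracking_params()) {
  n <- nrow(regions_t); m <- nrow(regions_t1)
  D2 <- params$max_link_distance^2
  if (n == 0L || m == 0L) {
    return(list(matches = data.frame(i = integer(), j = integer(),
                                     cost = double()),
                unmatched_t = seq_len(n), unmatched_t1 = seq_len(m),
                total_cost = (n + m) * D2))
  }
  cost <- link_cost_matrix(regions_t, regions_t1, params)
  BIG <- 1e9
  full <- matrix(BIG, n + m, n + m)
  fin <- cost
  fin[!is.finite(fin)] <- BIG
  full[seq_len(n), seq_len(m)] <- fin
  for (i in seq_len(n)) full[i, m + i] <- D2          # row no-link
  for (j in seq_len(m)) full[n + j, j] <- D2          # column no-link
  full[(n + 1):(n + m), (m + 1):(m + n)] <- 0         # dummy-dummy
  assign <- cpp_lap(full)
  mi <- integer(0); mj <- integer(0)
  for (i in seq_len(n)) {
    j <- assign[i]
    if (j <= m && is.finite(cost[i, j])) { mi <- c(mi, i); mj <- c(mj, j) }
  }
  matches <- data.frame(i = mi, j = mj,
                        cost = if (length(mi)) cost[cbind(mi, mj)] else double())
  list(matches = matches,
       unmatched_t = setdiff(seq_len(n), mi),
       unmatched_t1 = setdiff(seq_len(m), mj),
       total_cost = sum(matches$cost) + D2 * (n - length(mi)) +
         D2 * (m - length(mj)))
}

auto_division_radius <- function(areas) {
  # twice the median cell diameter (area-equivalent disk)
  4 * sqrt(median(areas) / pi)
}

#' Build tracks from a label movie
#'
#' Frame-to-frame linear assignment ([link_frames()]), then a post-hoc
#' division pass on the unmatched track starts: a start within the division
#' search radius of a track present at the previous frame becomes a daughter
#' when either (a) that track itself went unmatched and a second start lies
#' within the radius, or (b) the track was linked onward to a region no
#' larger than `division_area_frac` of its previous area — the typical
#' parent-to-daughter mislink — in which case the link is cut and both small
#' regions become daughters. Finally gap closing joins a track ending at `t`
#' to one starting at `t' <= t + 1 + max_gap_frames` when the link cost
#' allows, with the distance allowance scaled by `(gap + 1)`.
#'
#' @param movie a [label_movie()].
#' @param params a [tracking_params()].
#' @return a track table: `track_id`, `frame`, `label`, `y`, `x`, `area`,
#'   `touches_border`, `parent_track` (0 = no parent). Track ids are
#'   renumbered 1..K by (start frame, start label).
#' @export
build_tracks <- function(movie, params = tracking_params()) {
  Tn <- n_frames(movie)
  regs <- lapply(seq_len(Tn) - 1L, function(t) region_table(movie, t))
  tid_of <- vector("list", Tn)       # per frame: track id per region row
  next_tid <- 0L
  parent_of <- integer(0)            # per track id
  start_frame <- integer(0); end_frame <- integer(0)
  start_idx <- integer(0); end_idx <- integer(0)
  new_track <- function(parent = 0L) {
    next_tid <<- next_tid + 1L
    parent_of[next_tid] <<- parent
    next_tid
  }
  n0 <- nrow(regs[[1]])
  tid_of[[1]] <- vapply(seq_len(n0), function(i) new_track(), integer(1))
  division_parents <- integer(0)
  for (t in seq_len(Tn - 1L)) {
    ra <- regs[[t]]; rb <- regs[[t + 1L]]
    lk <- link_frames(ra, rb, params)
    tb <- rep(NA_integer_, nrow(rb))
    match_of_i <- rep(NA_integer_, nrow(ra))
    if (nrow(lk$matches)) {
      tb[lk$matches$j] <- tid_of[[t]][lk$matches$i]
      match_of_i[lk$matches$i] <- lk$matches$j
    }
    starts <- lk$unmatched_t1
    if (length(starts) && nrow(ra)) {
      r_div <- params$division_search_radius
      if (is.null(r_div)) r_div <- auto_division_radius(ra$area)
      # enumerate division hypotheses (parent i; daughters j1, j2) where at
      # least one daughter is an unmatched start and the other may be the
      # parent's own onward link (the typical parent-to-daughter mislink,
      # which is then cut). Rank by the distance between the parent's last
      # centroid and the daughter midpoint — for a real division the parent
      # sat where its daughters now straddle — and accept greedily.
      hyp <- NULL
      for (i in seq_len(nrow(ra))) {
        dcand <- starts[sqrt((rb$y[starts] - ra$y[i])^2 +
                               (rb$x[starts] - ra$x[i])^2) <= r_div]
        dcand <- dcand[rb$area[dcand] <=
                         params$division_area_frac * ra$area[i]]
        jlink <- match_of_i[i]
        if (!is.na(jlink) &&
            rb$area[jlink] <= params$division_area_frac * ra$area[i])
          dcand <- c(dcand, jlink)
        if (length(dcand) < 2L) next
        prs <- utils::combn(sort(dcand), 2L)
        for (cc in seq_len(ncol(prs))) {
          j1 <- prs[1, cc]; j2 <- prs[2, cc]
          if (!is.na(jlink) && !jlink %in% c(j1, j2)) next
          my <- (rb$y[j1] + rb$y[j2]) / 2; mx <- (rb$x[j1] + rb$x[j2]) / 2
          hyp <- rbind(hyp, data.frame(
            i = i, j1 = j1, j2 = j2,
            score = sqrt((ra$y[i] - my)^2 + (ra$x[i] - mx)^2)))
        }
      }
      if (!is.null(hyp) && nrow(hyp)) {
        hyp <- hyp[order(hyp$score, hyp$i, hyp$j1), , drop = FALSE]
        used_i <- logical(nrow(ra)); used_j <- logical(nrow(rb))
        for (hh in seq_len(nrow(hyp))) {
          i <- hyp$i[hh]; j1 <- hyp$j1[hh]; j2 <- hyp$j2[hh]
          if (used_i[i] || used_j[j1] || used_j[j2]) next
          jlink <- match_of_i[i]
          if (!is.na(jlink)) {
            if (!jlink %in% c(j1, j2)) next  # parent links elsewhere
            match_of_i[i] <- NA_integer_     # cut the mislink
          }
          ptid <- tid_of[[t]][i]
          tb[j1] <- new_track(parent = ptid)
          tb[j2] <- new_track(parent = ptid)
          used_i[i] <- TRUE; used_j[c(j1, j2)] <- TRUE
          division_parents <- c(division_parents, ptid)
        }
      }
    }
    for (j in which(is.na(tb))) tb[j] <- new_track()
    tid_of[[t + 1L]] <- tb
  }
  # assemble rows
  rows <- do.call(rbind, lapply(seq_len(Tn), function(tt) {
    r <- regs[[tt]]
    if (!nrow(r)) return(NULL)
    cbind(data.frame(track_id = tid_of[[tt]]), r)
  }))
  rows$parent_track <- parent_of[rows$track_id]
  # gap closing
  if (params$max_gap_frames > 0 && next_tid > 1L) {
    info <- track_extents(rows)
    ends <- info[info$end < Tn - 1L & !info$track_id %in% division_parents, ]
    starts <- info[info$start > 0L &
                     rows$parent_track[match(info$track_id, rows$track_id)] == 0L, ]
    pairs <- NULL
    for (ei in seq_len(nrow(ends))) {
      e <- ends[ei, ]
      gap <- starts$start - e$end - 1L
      cand <- which(gap >= 1L & gap <= params$max_gap_frames &
                      starts$track_id != e$track_id)
      for (si in cand) {
        s <- starts[si, ]
        er <- rows[rows$track_id == e$track_id & rows$frame == e$end, ]
        sr <- rows[rows$track_id == s$track_id & rows$frame == s$start, ]
        d <- sqrt((er$y - sr$y)^2 + (er$x - sr$x)^2)
        allow <- params$max_link_distance * (gap[si] + 1L)
        if (d > allow) next
        relA <- abs(er$area - sr$area) / max(er$area, sr$area)
        # a gap bridges the same cell: its area must be comparable
        if (relA > 0.5) next
        pairs <- rbind(pairs, data.frame(
          end_tid = e$track_id, start_tid = s$track_id,
          cost = d^2 * (1 + params$area_weight * relA)))
      }
    }
    if (!is.null(pairs) && nrow(pairs)) {
      pairs <- pairs[order(pairs$cost, pairs$end_tid, pairs$start_tid), ]
      used_end <- integer(0); used_start <- integer(0)
      remap <- seq_len(next_tid)
      for (pi in seq_len(nrow(pairs))) {
        p <- pairs[pi, ]
        if (p$end_tid %in% used_end || p$start_tid %in% used_start) next
        used_end <- c(used_end, p$end_tid)
        used_start <- c(used_start, p$start_tid)
        remap[p$start_tid] <- p$end_tid
      }
      # resolve chains a<-b<-c
      for (k in seq_len(next_tid)) {
        r <- k
        while (remap[r] != r) r <- remap[r]
        remap[k] <- r
      }
      rows$track_id <- remap[rows$track_id]
      rows$parent_track <- ifelse(rows$parent_track > 0L,
                                  remap[pmax(rows$parent_track, 1L)],
                                  0L)
    }
  }
  renumber_tracks(rows, dims = dim(movie$data))
}

track_extents <- function(tracks) {
  f <- factor(tracks$track_id)
  data.frame(track_id = as.integer(levels(f)),
             start = as.integer(tapply(tracks$frame, f, min)),
             end = as.integer(tapply(tracks$frame, f, max)),
             n = as.integer(tapply(tracks$frame, f, length)))
}

renumber_tracks <- function(rows, dims = attr(rows, "dims")) {
  ext <- track_extents(rows)
  first_lab <- vapply(ext$track_id, function(tid) {
    sub <- rows[rows$track_id == tid, ]
    sub$label[which.min(sub$frame)]
  }, integer(1))
  ord <- order(ext$start, first_lab)
  remap <- integer(max(ext$track_id))
  remap[ext$track_id[ord]] <- seq_along(ord)
  rows$track_id <- remap[rows$track_id]
  rows$parent_track <- ifelse(rows$parent_track > 0L,
                              remap[pmax(rows$parent_track, 1L)], 0L)
  rows <- rows[order(rows$track_id, rows$frame), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "dims") <- dims
  rows
}

#' Relink tracks locally after an edit
#'
#' For every touched label at `frame`, the regions of frames `frame - 1` and
#' `frame + 1` with maximal pixel-overlap fraction (relative to the smaller
#' region) are found; at or above `overlap_min` the label inherits the
#' predecessor's track id and the successor chain is relabelled to match,
#' otherwise a fresh track id is opened. Only tracks intersecting the edited
#' frame's neighbourhood are modified.
#'
#' @param movie the movie, already reflecting the edit at `frame`.
#' @param tracks the track table to update.
#' @param frame 0-based edited frame.
#' @param touched labels to reconnect (must exist at `frame`).
#' @param params a [tracking_params()] (for `overlap_min`).
#' @return the updated track table.
#' @export
relink_after_edit <- function(movie, tracks, frame, touched,
                              params = tracking_params()) {
  reg <- region_table(movie, frame)
  touched <- sort(unique(as.integer(touched)))
  missing <- setdiff(touched, reg$label)
  if (length(missing))
    stop_usage("touched label(s) absent at frame ", frame, ": ",
               paste(missing, collapse = ", "))
  Tn <- n_frames(movie)
  m_now <- frame_matrix(movie, frame)
  # drop stale rows at the edited frame (touched labels and vanished labels)
  stale <- tracks$frame == frame &
    (tracks$label %in% touched | !tracks$label %in% reg$label)
  tracks <- tracks[!stale, , drop = FALSE]
  ov_prev <- if (frame > 0)
    cpp_overlap(m_now, frame_matrix(movie, frame - 1)) else NULL
  ov_next <- if (frame < Tn - 1)
    cpp_overlap(m_now, frame_matrix(movie, frame + 1)) else NULL
  area_at <- function(fr, lab)
    tracks$area[tracks$frame == fr & tracks$label == lab][1]
  track_at <- function(fr, lab) {
    v <- tracks$track_id[tracks$frame == fr & tracks$label == lab]
    if (length(v)) v[1] else NA_integer_
  }
  best_overlap <- function(ov, L, areaL, other_frame) {
    sub <- ov[ov$a == L, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    fr <- vapply(seq_len(nrow(sub)), function(k) {
      ao <- area_at(other_frame, sub$b[k])
      if (is.na(ao)) return(0)
      sub$n[k] / min(areaL, ao)
    }, double(1))
    k <- which.max(fr)
    if (fr[k] < params$overlap_min) return(NULL)
    list(label = sub$b[k], frac = fr[k])
  }
  next_free <- max(tracks$track_id, 0L) + 1L
  claims <- list()
  for (L in touched) {
    areaL <- reg$area[reg$label == L]
    pred <- if (!is.null(ov_prev)) best_overlap(ov_prev, L, areaL, frame - 1)
            else NULL
    claims[[as.character(L)]] <-
      list(label = L, areaL = areaL,
           tid = if (is.null(pred)) NA_integer_
                 else track_at(frame - 1, pred$label),
           frac = if (is.null(pred)) 0 else pred$frac)
  }
  # resolve competing claims on the same predecessor track: best overlap wins
  ord <- order(-vapply(claims, `[[`, double(1), "frac"))
  taken <- tracks$track_id[tracks$frame == frame]   # untouched continuations
  new_rows <- NULL
  for (cl in claims[ord]) {
    tid <- cl$tid
    if (is.na(tid) || tid %in% taken) {
      tid <- next_free
      next_free <- next_free + 1L
      parent <- 0L
    } else {
      parent <- tracks$parent_track[match(tid, tracks$track_id)]
    }
    taken <- c(taken, tid)
    rr <- reg[reg$label == cl$label, ]
    new_rows <- rbind(new_rows, data.frame(
      track_id = tid, frame = frame, label = cl$label, area = rr$area,
      y = rr$y, x = rr$x, ymin = rr$ymin, xmin = rr$xmin, ymax = rr$ymax,
      xmax = rr$xmax, touches_border = rr$touches_border,
      parent_track = parent))
    # successor chain: relabel a track that starts right after the edit
    if (!is.null(ov_next)) {
      succ <- best_overlap(ov_next, cl$label, cl$areaL, frame + 1)
      if (!is.null(succ)) {
        tid_s <- track_at(frame + 1, succ$label)
        if (!is.na(tid_s) && tid_s != tid &&
            !any(tracks$track_id == tid_s & tracks$frame <= frame) &&
            !any(tracks$track_id == tid & tracks$frame > frame)) {
          tracks$track_id[tracks$track_id == tid_s] <- tid
        }
      }
    }
  }
  cols <- intersect(names(tracks), names(new_rows))
  extra <- setdiff(names(tracks), names(new_rows))
  if (length(extra)) for (e in extra) new_rows[[e]] <- NA
  tracks <- rbind(tracks, new_rows[, names(tracks), drop = FALSE])
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  tracks
}
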