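#' Parameters of the synthetic epithelium simulator
#'
#' The simulator emulates the regimes the curation pipeline is built for:
#' a confluent tissue of polygonal cells tiling the frame (a power-diagram
#' tessellation of Poisson-disk seeds), per-frame Brownian drift of the
#' seeds with persistent identity (so ground-truth tracks are exact by
#' construction), scheduled divisions with a programmed pre-division growth
#' of the relative apical area, scheduled extrusions with geometric apical
#' shrinkage, and a junction-bright intensity render with Gaussian noise.
#'
#' @param width,height frame size in pixels.
#' @param n_cells number of cells in frame 0.
#' @param n_frames number of frames.
#' @param drift_sigma per-frame Gaussian seed drift (px), truncated at
#'   2.5 sigma. The default 0.7 keeps honest frame-to-frame area and
#'   position fluctuations clearly below the default suspicion thresholds
#'   of [flag_config()], which is the regime the error-flagging model
#'   assumes (see the methods vignette).
#' @param n_divisions,n_extrusions scheduled event counts.
#' @param pre_division_growth factor by which a dividing cell's area,
#'   relative to the mean area of its neighbours, grows before division.
#' @param growth_frames frames over which the pre-division growth ramps.
#' @param extrusion_shrink_frames frames of apical shrinkage before an
#'   extrusion.
#' @param extrusion_shrink_factor per-frame area factor during shrinkage
#'   (0.6 brings the apical area to a few percent of its starting value
#'   within the window, so the final visible area is near zero).
#' @param intensity_noise_sigma Gaussian noise on the intensity render.
#' @param seed RNG seed; identical parameters and seed give bit-identical
#'   output.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(width = 200, height = 200, n_cells = 100,
                       n_frames = 30, drift_sigma = 0.7, n_divisions = 5,
                       n_extrusions = 5, pre_division_growth = 1.5,
                       growth_frames = 5, extrusion_shrink_frames = 5,
                       extrusion_shrink_factor = 0.6,
                       intensity_noise_sigma = 0.1, seed = 1) {
  p <- structure(as.list(environment()), class = "sim_params")
  n_events <- p$n_divisions + p$n_extrusions
  first <- max(p$growth_frames, p$extrusion_shrink_frames) + 1L
  last <- p$n_frames - 4L
  if (n_events > 0 && (last < first || (last - first) / 2 + 1 < n_events))
    stop_usage("cannot schedule ", n_events, " events in ", p$n_frames,
               " frames")
  p
}

poisson_disk_seeds <- function(n, h, w, margin = 3) {
  rmin <- 0.75 * sqrt(h * w / n)
  ys <- numeric(0); xs <- numeric(0)
  tries <- 0L
  while (length(ys) < n) {
    cy <- runif(1, margin, h - 1 - margin)
    cx <- runif(1, margin, w - 1 - margin)
    if (!length(ys) || min((ys - cy)^2 + (xs - cx)^2) >= rmin^2) {
      ys <- c(ys, cy); xs <- c(xs, cx)
    }
    tries <- tries + 1L
    if (tries > 200L * n) { rmin <- rmin * 0.85; tries <- 0L }
  }
  cbind(ys, xs)
}

# Digitisation can pinch a convex tessellation cell into several 4-connected
# fragments (thin slivers at the frame edge). Keep each label's largest
# fragment and absorb the others into their dominant neighbour, so the frame
# satisfies the one-region-per-label invariant. Returns the repaired frame
# and the labels whose pixel sets no longer follow the pure power-diagram
# geometry (donors and absorbers).
repair_connectivity <- function(m) {
  repaired <- integer(0)
  for (pass in 1:5) {
    comp <- cpp_components4(m)
    nz <- m != 0L
    ncomp_per <- tapply(comp[nz], m[nz], function(v) length(unique(v)))
    bad <- as.integer(names(ncomp_per)[ncomp_per > 1L])
    if (!length(bad)) break
    h <- nrow(m); w <- ncol(m)
    for (lab in bad) {
      cids <- table(comp[m == lab])
      keep <- as.integer(names(cids)[which.max(cids)])
      for (cid in setdiff(as.integer(names(cids)), keep)) {
        idx <- which(comp == cid)
        nb <- integer(0)
        for (p in idx) {
          y <- (p - 1L) %% h + 1L; x <- (p - 1L) %/% h + 1L
          for (q in c(if (y > 1) m[y - 1, x], if (y < h) m[y + 1, x],
                      if (x > 1) m[y, x - 1], if (x < w) m[y, x + 1]))
            if (q > 0 && q != lab) nb <- c(nb, q)
        }
        target <- if (length(nb)) {
          tb <- sort(table(nb), decreasing = TRUE)
          as.integer(names(tb)[1])
        } else 0L
        m[idx] <- target
        repaired <- c(repaired, lab, if (target > 0) target)
      }
    }
  }
  list(m = m, repaired = unique(repaired))
}

gaussian_blur <- function(m, sigma = 1) {
  band <- function(n) {
    B <- outer(seq_len(n), seq_len(n), function(i, j)
      exp(-(i - j)^2 / (2 * sigma^2)))
    B / rowSums(B)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

schedule_frames <- function(n, first, last, min_sep = 2L) {
  cand <- seq.int(first, last)
  for (attempt in 1:20) {
    picked <- integer(0)
    for (f in sample(cand)) {
      if (!length(picked) || min(abs(picked - f)) >= min_sep)
        picked <- c(picked, f)
      if (length(picked) == n) return(sort(picked))
    }
  }
  det <- seq.int(first, by = min_sep, length.out = n)
  if (n == 0) return(integer(0))
  if (det[n] <= last) return(det)
  stop_usage("could not schedule ", n, " event frames")
}

#' Simulate a confluent epithelium movie
#'
#' See [sim_params()] for the model. Returns the ground-truth label movie
#' (dense representation: labels are track ids, stable across frames), the
#' exact track table with lineage edges, the scheduled event list placed by
#' the same conventions the detectors use (divisions in the middle of the
#' two daughters at their first frame, extrusions at the last visible
#' centroid), and the intensity render. The seed positions and weights of
#' every frame travel on the movie as the `seed_table` attribute so that
#' error injection stays exactly invertible.
#'
#' @param params a [sim_params()].
#' @return `list(movie, tracks, events, intensity)`.
#' @export
simulate_epithelium <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  elong_frames <- 3L    # mitotic elongation: sub-seed phase before division
  with_seed(p$seed, {
    h <- p$height; w <- p$width; Tn <- p$n_frames
    sd0 <- poisson_disk_seeds(p$n_cells, h, w)
    # seeds: unique identity (seed_id) and the label currently rendered
    # (seed_lab). During mitotic elongation a dividing cell is carried by
    # two sub-seeds that still render the parent's label, so the division
    # frame changes only the labels, never the geometry.
    seed_id <- seq_len(p$n_cells)
    seed_lab <- seq_len(p$n_cells)
    sy <- sd0[, 1]; sx <- sd0[, 2]
    wt <- rep(0, p$n_cells)
    next_id <- p$n_cells
    margin <- 0.15 * min(h, w)
    interior <- seed_id[sy > margin & sy < h - 1 - margin &
                          sx > margin & sx < w - 1 - margin]
    n_ev <- p$n_divisions + p$n_extrusions
    if (n_ev > length(interior))
      stop_usage("not enough interior cells to schedule events")
    # extruding cells come from the at-most-median-size pool: apical
    # compaction to near zero within the shrink window is only attainable
    # without pathological per-frame jumps for cells of ordinary size
    areas0 <- tabulate(cpp_tessellate(h, w, sy, sx, wt), nbins = p$n_cells)
    small <- interior[areas0[interior] <= 1.05 * median(areas0)]
    if (p$n_extrusions > length(small))
      stop_usage("not enough small interior cells for extrusions")
    # events are kept spatially separated so their steering neighbourhoods
    # do not overlap: two events squeezing the same cells compound into
    # unscheduled area jumps
    dsep <- 2.2 * sqrt(h * w / p$n_cells)
    picked <- NULL
    for (relax in c(1, 0.85, 0.7, 0.55, 0.4, 0)) {
      dmin <- dsep * relax
      for (attempt in 1:30) {
        ex_try <- integer(0); dv_try <- integer(0)
        okdist <- function(i, chosen) !length(chosen) ||
          min(sqrt((sy[match(chosen, seed_id)] - sy[match(i, seed_id)])^2 +
                     (sx[match(chosen, seed_id)] - sx[match(i, seed_id)])^2)) >=
            dmin
        for (i in sample(small)) {
          if (length(ex_try) == p$n_extrusions) break
          if (okdist(i, c(ex_try, dv_try))) ex_try <- c(ex_try, i)
        }
        for (i in sample(setdiff(interior, ex_try))) {
          if (length(dv_try) == p$n_divisions) break
          if (okdist(i, c(ex_try, dv_try))) dv_try <- c(dv_try, i)
        }
        if (length(ex_try) == p$n_extrusions &&
            length(dv_try) == p$n_divisions) {
          picked <- list(ex = ex_try, dv = dv_try)
          break
        }
      }
      if (!is.null(picked)) break
    }
    if (is.null(picked)) stop_usage("could not place the scheduled events")
    ex_cells <- picked$ex
    dv_cells <- picked$dv
    first <- max(p$growth_frames, p$extrusion_shrink_frames) + 1L
    ev_frames <- schedule_frames(n_ev, first, Tn - 4L)
    ev_frames <- sample(ev_frames)     # random frame-to-cell pairing
    div <- data.frame(cell = dv_cells,
                      frame = ev_frames[seq_len(p$n_divisions)])
    extr <- data.frame(cell = ex_cells,
                       frame = ev_frames[p$n_divisions +
                                           seq_len(p$n_extrusions)])
    movie_arr <- array(0L, dim = c(Tn, h, w))
    track_rows <- vector("list", Tn)
    seed_rows <- vector("list", Tn)
    intens <- array(0, dim = c(Tn, h, w))
    events <- empty_event_list()
    parent_of <- integer(0)
    daughters_of <- list()
    div_release <- list()
    sep_pairs <- list()                # sister seeds still moving apart
    repaired_rows <- list()
    prev_area <- NULL                  # label-level areas of frame t-1
    for (t in seq_len(Tn) - 1L) {
      if (t > 0) {
        cap <- 2.5 * p$drift_sigma
        dy <- pmin(pmax(rnorm(length(sy), 0, p$drift_sigma), -cap), cap)
        dx <- pmin(pmax(rnorm(length(sx), 0, p$drift_sigma), -cap), cap)
        sy <- pmin(pmax(sy + dy, 3), h - 4)
        sx <- pmin(pmax(sx + dx, 3), w - 4)
        # excluded-volume constraint: near-coincident seeds make their
        # shared boundary flip wildly from frame to frame
        r_min <- 0.5 * sqrt(h * w / p$n_cells)
        for (rep_it in 1:3) {
          dmat <- as.matrix(stats::dist(cbind(sy, sx)))
          diag(dmat) <- Inf
          close_pairs <- which(dmat < r_min, arr.ind = TRUE)
          close_pairs <- close_pairs[close_pairs[, 1] < close_pairs[, 2], ,
                                     drop = FALSE]
          if (!nrow(close_pairs)) break
          # sister sub-seeds separate at their own pace, not by projection
          sis <- vapply(seq_len(nrow(close_pairs)), function(pr) {
            a <- seed_id[close_pairs[pr, 1]]; b <- seed_id[close_pairs[pr, 2]]
            any(vapply(sep_pairs, function(e)
              t <= e$until + 2L && all(c(a, b) %in% e$dg), logical(1)))
          }, logical(1))
          close_pairs <- close_pairs[!sis, , drop = FALSE]
          if (!nrow(close_pairs)) break
          for (pr in seq_len(nrow(close_pairs))) {
            i1 <- close_pairs[pr, 1]; i2 <- close_pairs[pr, 2]
            vy <- sy[i1] - sy[i2]; vx <- sx[i1] - sx[i2]
            d <- sqrt(vy^2 + vx^2)
            if (d < 0.1) { vy <- 1; vx <- 0; d <- 1 }
            push <- (r_min - d) / 2
            sy[i1] <- min(max(sy[i1] + push * vy / d, 3), h - 4)
            sx[i1] <- min(max(sx[i1] + push * vx / d, 3), w - 4)
            sy[i2] <- min(max(sy[i2] - push * vy / d, 3), h - 4)
            sx[i2] <- min(max(sx[i2] - push * vx / d, 3), w - 4)
          }
        }
      }
      # mitotic elongation onset: replace the parent seed by two sub-seeds
      # along the cell's long axis (Hertwig's rule), still labelled parent
      for (k in which(div$frame == t + elong_frames)) {
        pid <- div$cell[k]
        i <- match(pid, seed_id)
        ang <- runif(1, 0, 2 * pi)
        if (t > 0) {
          mp <- matrix(movie_arr[t, , ], h, w)
          pidx <- which(mp == pid)
          if (length(pidx) > 10) {
            pys <- (pidx - 1L) %% h; pxs <- (pidx - 1L) %/% h
            ang <- region_orientation(pys, pxs)
          }
        }
        pa <- if (!is.null(prev_area) && !is.na(prev_area[as.character(pid)]))
          prev_area[as.character(pid)] else h * w / p$n_cells
        delta <- 0.2 * sqrt(pa / pi)
        d1 <- next_id + 1L; d2 <- next_id + 2L; next_id <- next_id + 2L
        ny <- c(sy[i] + delta * sin(ang), sy[i] - delta * sin(ang))
        nx <- c(sx[i] + delta * cos(ang), sx[i] - delta * cos(ang))
        w0 <- wt[i]
        seed_id <- c(seed_id[-i], d1, d2)
        seed_lab <- c(seed_lab[-i], pid, pid)
        sy <- c(sy[-i], pmin(pmax(ny, 3), h - 4))
        sx <- c(sx[-i], pmin(pmax(nx, 3), w - 4))
        wt <- c(wt[-i], w0 / 2, w0 / 2)
        parent_of[c(d1, d2)] <- pid
        daughters_of[[as.character(pid)]] <- c(d1, d2)
        sep_pairs[[as.character(pid)]] <- list(dg = c(d1, d2),
                                               until = div$frame[k] + 3L)
      }
      # division frame: the sub-seeds take their own labels; the footprint
      # they inherited from the parent is released gradually
      for (k in which(div$frame == t)) {
        pid <- div$cell[k]
        dg <- daughters_of[[as.character(pid)]]
        seed_lab[match(dg, seed_id)] <- dg
        A0 <- if (!is.null(prev_area)) prev_area[as.character(pid)] else NA
        div_release[[as.character(pid)]] <- list(
          dg = dg, A0 = if (is.na(A0)) h * w / p$n_cells else A0,
          t0 = t, k = 4L)
      }
      # sister separation (cytokinesis relaxation)
      for (e in sep_pairs) {
        if (t > e$until || !all(e$dg %in% seed_id)) next
        i1 <- match(e$dg[1], seed_id); i2 <- match(e$dg[2], seed_id)
        vy <- sy[i1] - sy[i2]; vx <- sx[i1] - sx[i2]
        nv <- sqrt(vy^2 + vx^2)
        if (nv > 0.1) {
          vy <- vy / nv; vx <- vx / nv
          sy[i1] <- min(max(sy[i1] + 1.2 * vy, 3), h - 4)
          sx[i1] <- min(max(sx[i1] + 1.2 * vx, 3), w - 4)
          sy[i2] <- min(max(sy[i2] - 1.2 * vy, 3), h - 4)
          sx[i2] <- min(max(sx[i2] - 1.2 * vx, 3), w - 4)
        }
      }
      # extrusions past their last visible frame: remove the seed
      for (k in which(extr$frame == t - 1L)) {
        i <- match(extr$cell[k], seed_id)
        if (!is.na(i)) {
          seed_id <- seed_id[-i]; seed_lab <- seed_lab[-i]
          sy <- sy[-i]; sx <- sx[-i]; wt <- wt[-i]
        }
      }
      # steering targets for this frame
      grow <- div[div$frame - p$growth_frames <= t & t < div$frame, ,
                  drop = FALSE]
      shrink <- extr[extr$frame - p$extrusion_shrink_frames < t &
                       t <= extr$frame, , drop = FALSE]
      release <- Filter(function(e) all(e$dg %in% seed_id) && t <= e$t0 + e$k,
                        div_release)
      steering <- nrow(grow) > 0 || nrow(shrink) > 0 || length(release) > 0
      if (is.null(div_ref <- attr(div, "ref"))) div_ref <- list()
      lab_idx <- NULL
      adj <- NULL
      for (iter in seq_len(if (steering) 10L else 1L)) {
        lab_idx <- cpp_tessellate(h, w, sy, sx, wt)
        areas <- tabulate(lab_idx, nbins = length(seed_id))
        if (any(areas < 8)) {          # keep every living seed visible
          wt[areas < 8] <- wt[areas < 8] + 15
          next
        }
        if (!steering) break
        lab_area <- tapply(areas, seed_lab, sum)
        if (is.null(adj)) adj <- cpp_adjacency(lab_idx, 2L)
        for (k in seq_len(nrow(grow))) {
          pid <- grow$cell[k]
          js <- which(seed_lab == pid)
          nbs <- setdiff(c(adj$b[adj$a %in% js], adj$a[adj$b %in% js]), js)
          nb_labs <- unique(seed_lab[nbs])
          if (!length(nb_labs)) next
          nb_mean <- mean(lab_area[as.character(nb_labs)])
          key <- as.character(pid)
          if (is.null(div_ref[[key]]))
            div_ref[[key]] <- as.numeric(lab_area[key]) / nb_mean
          # ramp the relative area from the cell's own starting ratio to
          # the programmed pre-division value
          step <- t - (grow$frame[k] - p$growth_frames) + 1L
          rt <- div_ref[[key]] +
            (p$pre_division_growth - div_ref[[key]]) * step / p$growth_frames
          target <- rt * nb_mean
          for (j in js)
            wt[j] <- wt[j] + 0.5 * (target / length(js) - areas[j]) / pi
        }
        for (e in release) {
          js <- match(e$dg, seed_id)
          nbs <- setdiff(c(adj$b[adj$a %in% js], adj$a[adj$b %in% js]), js)
          nb_labs <- unique(seed_lab[nbs])
          a_nat <- if (length(nb_labs))
            2 * mean(lab_area[as.character(nb_labs)]) else e$A0
          frac <- min(1, (t - e$t0 + 1) / (e$k + 1))
          combined <- e$A0 + (a_nat - e$A0) * frac
          for (j in js)
            wt[j] <- wt[j] + 0.5 * (combined / 2 - areas[j]) / pi
        }
        for (k in seq_len(nrow(shrink))) {
          i <- which(seed_lab == shrink$cell[k])
          key <- as.character(shrink$cell[k])
          # chain the shrink schedule off the last observed area so the
          # realised frame-to-frame ratio follows the programmed factor
          prev <- if (!is.null(prev_area) && !is.na(prev_area[key]))
            prev_area[key] else areas[i]
          target <- max(p$extrusion_shrink_factor * prev, 10)
          wt[i] <- wt[i] + 0.7 * (target - areas[i]) / pi
        }
      }
      attr(div, "ref") <- div_ref
      m <- matrix(as.integer(seed_lab[lab_idx]), h, w)
      rep_out <- repair_connectivity(m)
      m <- rep_out$m
      if (length(rep_out$repaired))
        repaired_rows[[length(repaired_rows) + 1L]] <-
          data.frame(frame = t, label = rep_out$repaired)
      movie_arr[t + 1L, , ] <- m
      reg <- region_table_matrix(m, t)
      track_rows[[t + 1L]] <- reg
      # per-label seed record; labels carried by two sub-seeds get weight NA
      # (their geometry is not a single power cell)
      sr <- data.frame(frame = t,
                       label = as.integer(names(table(seed_lab))))
      sr$sy <- as.numeric(tapply(sy, seed_lab, mean)[as.character(sr$label)])
      sr$sx <- as.numeric(tapply(sx, seed_lab, mean)[as.character(sr$label)])
      nsd <- as.integer(table(seed_lab)[as.character(sr$label)])
      w1 <- as.numeric(tapply(wt, seed_lab, function(v) v[1])[
        as.character(sr$label)])
      sr$weight <- ifelse(nsd > 1L, NA_real_, w1)
      seed_rows[[t + 1L]] <- sr
      areas_now <- tabulate(lab_idx, nbins = length(seed_id))
      prev_area <- tapply(areas_now, seed_lab, sum)
      names(prev_area) <- as.character(names(prev_area))
      # event records placed by the detector conventions
      for (k in which(div$frame == t)) {
        dg <- daughters_of[[as.character(div$cell[k])]]
        r1 <- reg[reg$label == dg[1], ]; r2 <- reg[reg$label == dg[2], ]
        events <- rbind(events, data.frame(
          event_id = nrow(events) + 1L, kind = "division", frame = t,
          y = (r1$y + r2$y) / 2, x = (r1$x + r2$x) / 2,
          parent_track = div$cell[k], daughter1 = min(dg),
          daughter2 = max(dg)))
      }
      for (k in which(extr$frame == t)) {
        r <- reg[reg$label == extr$cell[k], ]
        events <- rbind(events, data.frame(
          event_id = nrow(events) + 1L, kind = "extrusion", frame = t,
          y = r$y, x = r$x, parent_track = extr$cell[k],
          daughter1 = NA_integer_, daughter2 = NA_integer_))
      }
      # junction-bright intensity render
      bound <- cpp_junction_band(m)
      base <- 0.1 + 0.9 * gaussian_blur(matrix(as.numeric(bound), h, w), 1)
      intens[t + 1L, , ] <- base + rnorm(h * w, 0, p$intensity_noise_sigma)
    }
    tracks <- do.call(rbind, track_rows)
    tracks <- cbind(data.frame(track_id = tracks$label), tracks)
    tracks$parent_track <- ifelse(
      tracks$track_id <= length(parent_of) & !is.na(parent_of[tracks$track_id]),
      parent_of[tracks$track_id], 0L)
    tracks$parent_track[is.na(tracks$parent_track)] <- 0L
    tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
    rownames(tracks) <- NULL
    attr(tracks, "dims") <- dim(movie_arr)
    movie <- label_movie(movie_arr)
    attr(movie, "seed_table") <- do.call(rbind, seed_rows)
    attr(movie, "repaired") <- if (length(repaired_rows))
      do.call(rbind, repaired_rows)
    else data.frame(frame = integer(), label = integer())
    events$event_id <- seq_len(nrow(events))
    list(movie = movie, tracks = tracks, events = events, intensity = intens)
  })
}

#' Synthetic event-probability movie
#'
#' Gaussian bumps of amplitude 1 at the given events' spatiotemporal
#' positions: a stand-in for the probability maps of an external
#' deep-learning event detector that fires exactly at the true events.
#'
#' @param events an event table (filter by `kind` for per-class channels).
#' @param dims `c(T, Y, X)` geometry.
#' @param sigma_px spatial bump width (px).
#' @param frames_halfwidth temporal half-extent of each bump (frames).
#' @return a `T x Y x X` array in \[0, 1\].
#' @export
event_probability_movie <- function(events, dims, sigma_px = 3,
                                    frames_halfwidth = 1) {
  arr <- array(0, dim = dims)
  if (!nrow(events)) return(arr)
  yy <- matrix(seq_len(dims[2]) - 1, dims[2], dims[3])
  xx <- matrix(seq_len(dims[3]) - 1, dims[2], dims[3], byrow = TRUE)
  for (k in seq_len(nrow(events))) {
    bump <- exp(-((yy - events$y[k])^2 + (xx - events$x[k])^2) /
                  (2 * sigma_px^2))
    for (t in (events$frame[k] - frames_halfwidth):
         (events$frame[k] + frames_halfwidth)) {
      if (t < 0 || t >= dims[1]) next
      arr[t + 1, , ] <- pmax(arr[t + 1, , ], bump)
    }
  }
  arr
}

#' Corruption parameters
#'
#' Independent per-(frame, cell) probabilities of injecting each error
#' kind of the classic taxonomy: false splits, false merges, one-frame
#' dropouts and track-identity swaps.
#'
#' @param p_split,p_merge,p_dropout,p_swap injection probabilities.
#' @param seed RNG seed of the corruption stream (separate from the
#'   simulation seed so error patterns vary on a fixed tissue).
#' @return a list of class `corruption_params`.
#' @export
corruption_params <- function(p_split = 0.02, p_merge = 0.02,
                              p_dropout = 0.02, p_swap = 0.02, seed = 7) {
  stopifnot(p_split >= 0, p_merge >= 0, p_dropout >= 0, p_swap >= 0,
            p_split + p_merge + p_dropout + p_swap <= 1)
  structure(list(p_split = p_split, p_merge = p_merge, p_dropout = p_dropout,
                 p_swap = p_swap, seed = seed),
            class = "corruption_params")
}

#' Inject invertible segmentation and tracking errors
#'
#' Draws independently per (frame, cell) and injects: a false split (random
#' chord through the centroid), a false merge (absorb the neighbour with the
#' longest shared boundary), a one-frame dropout (cell becomes background),
#' or a track-id swap with a neighbour (from that frame onward). Every
#' injection is logged with its full parameters and the returned
#' [edit_script()] (the inverses in reverse order) restores the ground
#' truth bit-exactly through [apply_edit_script()].
#'
#' Cells are skipped when an exact inverse cannot be guaranteed or when the
#' error would be confounded with a real event: cells already corrupted in
#' the +/-1-frame window, cells with steered (nonzero-weight) seeds for a
#' merge, and — when `events` is supplied — the event tracks themselves plus
#' all cells near an event's spatiotemporal position.
#'
#' @param movie,tracks simulator output (the movie's `seed_table` attribute
#'   makes merge inversion exact; without it, region centroids are used and
#'   inversion is only approximate).
#' @param params a [corruption_params()].
#' @param events optional ground-truth events to shield (see above).
#' @param event_shield_px,event_shield_frames spatiotemporal shielding
#'   radius around events. The defaults cover the reach of the default
#'   probability-map filter window ([event_params()]), so an injected error
#'   can never fall inside the region where an external detector would
#'   corroborate it.
#' @return `list(movie, tracks, log, inverse)`.
#' @export
corrupt_movie <- function(movie, tracks, params = corruption_params(),
                          events = NULL, event_shield_px = 30,
                          event_shield_frames = 4) {
  p <- params
  Tn <- n_frames(movie)
  seed_tab <- attr(movie, "seed_table")
  repaired_tab <- attr(movie, "repaired")
  with_seed(p$seed, {
    locked <- new.env(hash = TRUE)
    lock <- function(fr, lab) {
      for (f in max(0, fr - 1):min(Tn - 1, fr + 1))
        assign(paste0(f, ":", lab), TRUE, envir = locked)
    }
    lock_one <- function(fr, lab)
      assign(paste0(fr, ":", lab), TRUE, envir = locked)
    is_locked <- function(fr, lab)
      exists(paste0(fr, ":", lab), envir = locked)
    locked_tracks <- integer(0)
    if (!is.null(events) && nrow(events)) {
      locked_tracks <- unique(c(events$parent_track, events$daughter1,
                                events$daughter2))
      locked_tracks <- locked_tracks[!is.na(locked_tracks)]
      for (k in seq_len(nrow(events))) {
        sel <- abs(tracks$frame - events$frame[k]) <= event_shield_frames &
          sqrt((tracks$y - events$y[k])^2 + (tracks$x - events$x[k])^2) <=
            event_shield_px
        for (r in which(sel)) lock_one(tracks$frame[r], tracks$label[r])
      }
    }
    # swaps permute labels from their frame onward: `perm` maps a current
    # label to the ground-truth label whose seed describes its geometry
    perm <- seq_len(max(movie$data) * 2L)
    gt_of <- function(lab) if (lab <= length(perm)) perm[lab] else lab
    # TRUE when the cell is a single unweighted power cell whose boundary
    # with an equal neighbour is the exact seed bisector
    plain_cell <- function(fr, lab) {
      if (is.null(seed_tab)) return(TRUE)
      v <- seed_tab$weight[seed_tab$frame == fr & seed_tab$label == gt_of(lab)]
      length(v) > 0 && !is.na(v[1]) && v[1] == 0
    }
    has_seed <- function(fr, lab) {
      !is.null(seed_tab) &&
        any(seed_tab$frame == fr & seed_tab$label == gt_of(lab))
    }
    was_repaired <- function(fr, lab) {
      !is.null(repaired_tab) && nrow(repaired_tab) &&
        any(repaired_tab$frame == fr & repaired_tab$label == gt_of(lab))
    }
    seed_at <- function(fr, lab) {
      if (!is.null(seed_tab)) {
        r <- which(seed_tab$frame == fr & seed_tab$label == gt_of(lab))
        if (length(r)) return(c(seed_tab$sy[r[1]], seed_tab$sx[r[1]]))
      }
      row <- tracks[tracks$frame == fr & tracks$label == lab, ]
      c(row$y[1], row$x[1])
    }
    log <- NULL
    inverse_ops <- list()
    next_label <- max(movie$data) + 1L
    frames <- if (Tn >= 3) 1:(Tn - 2) else 0:(Tn - 1)
    for (f in frames) {
      m <- frame_matrix(movie, f)
      adj <- NULL
      present <- function(fr, lab)
        fr < 0 || fr > Tn - 1 ||
          any(tracks$frame == fr & tracks$label == lab)
      for (lab in sort(unique(as.vector(m[m > 0])))) {
        if (is_locked(f, lab) || lab %in% locked_tracks) next
        if (!present(f - 1, lab) || !present(f + 1, lab)) next
        u <- runif(1)
        kind <- if (u < p$p_split) "split"
        else if (u < p$p_split + p$p_merge) "merge"
        else if (u < p$p_split + p$p_merge + p$p_dropout) "dropout"
        else if (u < p$p_split + p$p_merge + p$p_dropout + p$p_swap) "swap"
        else next
        row_i <- which(tracks$frame == f & tracks$label == lab)
        areas_f <- tracks$area[tracks$frame == f]
        if (kind == "split") {
          if (tracks$area[row_i] < 0.8 * median(areas_f)) next
          idx <- which(m == lab)
          ys <- (idx - 1L) %% nrow(m); xs <- (idx - 1L) %/% nrow(m)
          cy <- mean(ys); cx <- mean(xs)
          done <- FALSE
          for (try in 1:8) {
            ang <- runif(1, 0, pi)
            sideB <- (ys - cy) * cos(ang) + (xs - cx) * sin(ang) > 0
            if (sum(sideB) < 4 || sum(!sideB) < 4) next
            m2 <- m
            m2[idx[sideB]] <- next_label
            comp <- cpp_components4(m2)
            if (length(unique(comp[m2 == lab])) != 1L ||
                length(unique(comp[m2 == next_label])) != 1L) next
            m <- m2
            done <- TRUE
            break
          }
          if (!done) next
          movie <- set_frame_matrix(movie, f, m)
          regB <- region_table_matrix(m, f)
          rB <- regB[regB$label == next_label, ]
          rA <- regB[regB$label == lab, ]
          for (col in c("area", "y", "x", "ymin", "xmin", "ymax", "xmax",
                        "touches_border"))
            tracks[row_i, col] <- rA[[col]]
          newrow <- tracks[row_i, , drop = FALSE]
          newrow$track_id <- next_label; newrow$label <- next_label
          newrow$parent_track <- 0L
          for (col in c("area", "y", "x", "ymin", "xmin", "ymax", "xmax",
                        "touches_border"))
            newrow[[col]] <- rB[[col]]
          tracks <- rbind(tracks, newrow)
          log <- rbind(log, data.frame(kind = "split", frame = f, label = lab,
                                       other = next_label))
          inverse_ops[[length(inverse_ops) + 1L]] <-
            list(op = "merge", frame = f, label_a = lab, label_b = next_label)
          lock(f, lab); lock(f, next_label)
          next_label <- next_label + 1L
        } else if (kind == "merge") {
          if (!has_seed(f, lab) || !plain_cell(f, lab) ||
              was_repaired(f, lab)) next
          if (is.null(adj)) adj <- cpp_adjacency(m, 2L)
          nb <- adj[adj$a == lab | adj$b == lab, , drop = FALSE]
          if (!nrow(nb)) next
          nb$other <- ifelse(nb$a == lab, nb$b, nb$a)
          ok <- vapply(nb$other, function(o)
            !is_locked(f, o) && !o %in% locked_tracks &&
              present(f - 1, o) && present(f + 1, o) &&
              has_seed(f, o) && plain_cell(f, o) &&
              !was_repaired(f, o), logical(1))
          nb <- nb[ok, , drop = FALSE]
          if (!nrow(nb)) next
          partner <- nb$other[order(-nb$contact, nb$other)][1]
          sA <- seed_at(f, lab); sP <- seed_at(f, partner)
          labs <- sort(c(lab, partner))
          seeds <- if (labs[1] == lab) rbind(sA, sP) else rbind(sP, sA)
          m[m == partner] <- lab
          movie <- set_frame_matrix(movie, f, m)
          regM <- region_table_matrix(m, f)
          rA <- regM[regM$label == lab, ]
          for (col in c("area", "y", "x", "ymin", "xmin", "ymax", "xmax",
                        "touches_border"))
            tracks[row_i, col] <- rA[[col]]
          tracks <- tracks[!(tracks$frame == f & tracks$label == partner), ,
                           drop = FALSE]
          log <- rbind(log, data.frame(kind = "merge", frame = f, label = lab,
                                       other = partner))
          inverse_ops[[length(inverse_ops) + 1L]] <-
            list(op = "split", frame = f, label = lab,
                 seeds = unname(seeds), part_labels = labs,
                 relief = "nearest_seed")
          lock(f, lab); lock(f, partner)
        } else if (kind == "dropout") {
          idx <- which(m == lab)
          ys <- (idx - 1L) %% nrow(m); xs <- (idx - 1L) %/% nrow(m)
          # the hole must be exactly this cell: no adjacent background
          touch_bg <- FALSE
          h <- nrow(m); w <- ncol(m)
          for (k in seq_along(idx)) {
            y <- ys[k] + 1L; x <- xs[k] + 1L
            if ((y > 1 && m[y - 1, x] == 0L) || (y < h && m[y + 1, x] == 0L) ||
                (x > 1 && m[y, x - 1] == 0L) || (x < w && m[y, x + 1] == 0L)) {
              touch_bg <- TRUE; break
            }
          }
          if (touch_bg) next
          if (is.null(adj)) adj <- cpp_adjacency(m, 2L)
          nbl <- unique(c(adj$b[adj$a == lab], adj$a[adj$b == lab]))
          ksd <- which.min(ys * 1e6 + xs)   # stable seed pixel for refilling
          m[idx] <- 0L
          movie <- set_frame_matrix(movie, f, m)
          tracks <- tracks[-row_i, , drop = FALSE]
          log <- rbind(log, data.frame(kind = "dropout", frame = f,
                                       label = lab, other = NA_integer_))
          inverse_ops[[length(inverse_ops) + 1L]] <-
            list(op = "fill", frame = f, seed = c(ys[ksd], xs[ksd]),
                 label = lab)
          lock(f, lab)
          for (o in nbl) lock_one(f, o)
        } else {                       # swap
          if (is.null(adj)) adj <- cpp_adjacency(m, 2L)
          nb <- adj[adj$a == lab | adj$b == lab, , drop = FALSE]
          if (!nrow(nb)) next
          nb$other <- ifelse(nb$a == lab, nb$b, nb$a)
          ok <- vapply(nb$other, function(o)
            !is_locked(f, o) && !o %in% locked_tracks &&
              present(f - 1, o) && present(f + 1, o), logical(1))
          cand <- sort(nb$other[ok])
          if (!length(cand)) next
          partner <- cand[floor(runif(1) * length(cand)) + 1L]
          sw <- swap_tracks(movie, tracks, f, lab, partner)
          movie <- sw$movie; tracks <- sw$tracks
          tmp <- perm[lab]; perm[lab] <- perm[partner]; perm[partner] <- tmp
          log <- rbind(log, data.frame(kind = "swap", frame = f, label = lab,
                                       other = partner))
          inverse_ops[[length(inverse_ops) + 1L]] <-
            list(op = "swap", frame = f, track_a = lab, track_b = partner)
          lock(f, lab); lock(f, partner)
          m <- frame_matrix(movie, f)
        }
      }
    }
    if (is.null(log))
      log <- data.frame(kind = character(), frame = integer(),
                        label = integer(), other = integer())
    inverse <- edit_script(rev(inverse_ops))
    tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
    rownames(tracks) <- NULL
    attr(movie, "seed_table") <- NULL
    attr(movie, "repaired") <- NULL
    list(movie = movie, tracks = tracks, log = log, inverse = inverse)
  })
}
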