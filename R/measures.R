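# Cell-scale and track-scale feature measurement.

CROFTON4_COEFS <- c(0, pi / 4 * (1 + 1 / sqrt(2)), pi / (4 * sqrt(2)),
                    pi / (2 * sqrt(2)), 0, pi / 4 * (1 + 1 / sqrt(2)), 0,
                    pi / (4 * sqrt(2)), pi / 4, pi / 2, pi / (4 * sqrt(2)),
                    pi / (4 * sqrt(2)), pi / 4, pi / 2, 0, 0)

crofton_perimeter <- function(mask) {
  # 4-direction Cauchy-Crofton estimate from 2x2 pixel configurations
  h <- nrow(mask); w <- ncol(mask)
  P <- matrix(0L, h + 2L, w + 2L)
  P[2:(h + 1), 2:(w + 1)] <- mask
  tl <- P[1:(h + 1), 1:(w + 1)]; tr <- P[1:(h + 1), 2:(w + 2)]
  bl <- P[2:(h + 2), 1:(w + 1)]; br <- P[2:(h + 2), 2:(w + 2)]
  code <- 8L * tl + 2L * tr + 4L * bl + br
  cnt <- tabulate(code + 1L, nbins = 16L)
  sum(CROFTON4_COEFS * cnt)
}

hull_perimeter <- function(ys, xs) {
  # perimeter of the convex hull of the pixel squares (corner points),
  # reduced by (4 - pi): converts the square-offset Minkowski term of the
  # outer crack boundary into the isotropic half-pixel offset
  pts <- cbind(c(ys - 0.5, ys - 0.5, ys + 0.5, ys + 0.5),
               c(xs - 0.5, xs + 0.5, xs - 0.5, xs + 0.5))
  hull <- grDevices::chull(pts)
  hp <- pts[c(hull, hull[1]), , drop = FALSE]
  sum(sqrt(diff(hp[, 1])^2 + diff(hp[, 2])^2)) - (4 - pi)
}

# Region perimeter: the larger of the Crofton-4 estimate and the corrected
# convex-hull perimeter. Crofton alone systematically underestimates
# axis-aligned polygonal boundaries (a 10x10 square comes out at 36.8, not
# 40); the hull term restores polygon lengths for convex cells while Crofton
# dominates for concave ones (a region's perimeter always bounds its hull's).
region_perimeter <- function(mask, ys, xs) {
  max(crofton_perimeter(mask), hull_perimeter(ys, xs))
}

region_orientation <- function(ys, xs) {
  my <- ys - mean(ys); mx <- xs - mean(xs)
  mu20 <- sum(my * my); mu02 <- sum(mx * mx); mu11 <- sum(my * mx)
  th <- 0.5 * atan2(2 * mu11, mu02 - mu20)   # angle from the x axis
  if (th <= -pi / 2) th <- th + pi
  if (th > pi / 2) th <- th - pi
  th
}

#' Measure cell-scale features
#'
#' Per (frame, label): `area` (pixel count), `perimeter` (Crofton/convex
#' hybrid estimate, see the methods vignette), `shape_index`
#' (perimeter / sqrt(area)), `NbNeighbor` (adjacency degree), `orientation`
#' (major-axis angle of the second-moment ellipse, radians in
#' (-pi/2, pi/2]), and, when an intensity movie is given,
#' `cytoplasmic_intensity` (mean over the region eroded by `ring_width`)
#' and `junctional_intensity` (mean over the boundary band of width
#' `ring_width`). The `neighbors` list column carries each cell's neighbour
#' labels for downstream relative-area analyses.
#'
#' @param movie a [label_movie()].
#' @param intensity optional `T x Y x X` intensity array.
#' @param features character vector of features to compute; default all
#'   available. Unknown names are an error.
#' @param tracks optional track table used to attach `track_id`.
#' @param groups optional data frame `track_id`, `group` (e.g.
#'   [fate_groups()] or [group_from_track_intensity()]) appended as a
#'   `group` column.
#' @param frames 0-based frames to measure (default all).
#' @param ring_width width in pixels of the junctional band (default 2).
#' @return a data frame, one row per (frame, label).
#' @export
cell_features <- function(movie, intensity = NULL, features = NULL,
                          tracks = NULL, groups = NULL, frames = NULL,
                          ring_width = 2) {
  all_feats <- c("area", "perimeter", "shape_index", "NbNeighbor",
                 "orientation", "neighbors", "cytoplasmic_intensity",
                 "junctional_intensity")
  if (is.null(features)) {
    features <- all_feats
    if (is.null(intensity))
      features <- setdiff(features, c("cytoplasmic_intensity",
                                      "junctional_intensity"))
  }
  unknown <- setdiff(features, all_feats)
  if (length(unknown))
    stop_usage("unknown feature(s): ", paste(unknown, collapse = ", "))
  need_int <- intersect(features, c("cytoplasmic_intensity",
                                    "junctional_intensity"))
  if (length(need_int) && is.null(intensity))
    stop_usage("intensity movie required for: ",
               paste(need_int, collapse = ", "))
  if (is.null(frames)) frames <- seq_len(n_frames(movie)) - 1L
  px <- movie$pixel_size
  out <- list()
  for (t in frames) {
    m <- frame_matrix(movie, t)
    reg <- region_table(movie, t)
    if (!nrow(reg)) next
    res <- reg[, c("frame", "label", "area")]
    res$area_um2 <- res$area * px^2
    adj <- NULL
    if (any(c("NbNeighbor", "neighbors") %in% features))
      adj <- cpp_adjacency(m, 2L)
    if ("NbNeighbor" %in% features)
      res$NbNeighbor <- as.integer(neighbor_degree(adj, reg$label))
    if ("neighbors" %in% features)
      res$neighbors <- lapply(reg$label, function(L)
        sort(c(adj$b[adj$a == L], adj$a[adj$b == L])))
    needs_px <- any(c("perimeter", "shape_index", "orientation",
                      "cytoplasmic_intensity",
                      "junctional_intensity") %in% features)
    if (needs_px) {
      intf <- if (!is.null(intensity)) {
        if (is.matrix(intensity)) intensity
        else {
          mm <- intensity[t + 1L, , , drop = TRUE]
          if (!is.matrix(mm)) mm <- matrix(mm, nrow(m), ncol(m))
          mm
        }
      }
      per <- ori <- cyt <- jun <- rep(NA_real_, nrow(reg))
      for (i in seq_len(nrow(reg))) {
        L <- reg$label[i]
        y0 <- reg$ymin[i] + 1L; y1 <- reg$ymax[i] + 1L
        x0 <- reg$xmin[i] + 1L; x1 <- reg$xmax[i] + 1L
        sub <- m[y0:y1, x0:x1, drop = FALSE] == L
        idx <- which(sub)
        ys <- (idx - 1L) %% nrow(sub); xs <- (idx - 1L) %/% nrow(sub)
        if (any(c("perimeter", "shape_index") %in% features))
          per[i] <- region_perimeter(sub, ys, xs)
        if ("orientation" %in% features) ori[i] <- region_orientation(ys, xs)
        if (length(need_int)) {
          ed <- cpp_edt(sub)
          vals <- intf[y0:y1, x0:x1, drop = FALSE]
          core <- sub & ed > ring_width
          band <- sub & ed <= ring_width
          cyt[i] <- if (any(core)) mean(vals[core]) else mean(vals[sub])
          jun[i] <- if (any(band)) mean(vals[band]) else mean(vals[sub])
        }
      }
      if ("perimeter" %in% features) res$perimeter <- per * px
      if ("shape_index" %in% features)
        res$shape_index <- per / sqrt(reg$area)
      if ("orientation" %in% features) res$orientation <- ori
      if ("cytoplasmic_intensity" %in% features)
        res$cytoplasmic_intensity <- cyt
      if ("junctional_intensity" %in% features) res$junctional_intensity <- jun
    }
    out[[length(out) + 1L]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame(frame = integer(), label = integer()))
  if (!is.null(tracks))
    res$track_id <- tracks$track_id[match(paste(res$frame, res$label),
                                          paste(tracks$frame, tracks$label))]
  if (!is.null(groups) && "track_id" %in% names(res)) {
    res$group <- groups$group[match(res$track_id, groups$track_id)]
    res$group[is.na(res$group)] <- "none"
  }
  rownames(res) <- NULL
  res
}

#' Measure track-scale features
#'
#' `duration` is the number of observed frames (and `duration_min` its
#' physical time), `avg_speed` the mean centroid displacement per frame
#' between consecutive observations, and `straightness` the net
#' displacement divided by the total path length (1 for a zero-length
#' path); straightness is 1 exactly for collinear monotone motion.
#'
#' @param tracks a track table.
#' @param movie optional [label_movie()] providing `frame_interval` and,
#'   with `intensity`, per-track mean intensity.
#' @param intensity optional `T x Y x X` intensity array.
#' @return a data frame `track_id`, `duration`, `duration_min`, `avg_speed`,
#'   `straightness` (and `mean_intensity` when intensity is given).
#' @export
track_features <- function(tracks, movie = NULL, intensity = NULL) {
  fi <- if (!is.null(movie)) movie$frame_interval else 1
  ids <- sort(unique(tracks$track_id))
  out <- lapply(ids, function(tid) {
    tr <- tracks[tracks$track_id == tid, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    n <- nrow(tr)
    if (n < 2) {
      return(data.frame(track_id = tid, duration = n, duration_min = n * fi,
                        avg_speed = 0, straightness = 1))
    }
    step <- sqrt(diff(tr$y)^2 + diff(tr$x)^2)
    dfr <- diff(tr$frame)
    total <- sum(step)
    net <- sqrt((tr$y[n] - tr$y[1])^2 + (tr$x[n] - tr$x[1])^2)
    data.frame(track_id = tid, duration = n, duration_min = n * fi,
               avg_speed = mean(step / dfr),
               straightness = if (total == 0) 1 else net / total)
  })
  res <- do.call(rbind, out)
  if (!is.null(intensity) && !is.null(movie)) {
    means <- track_region_means(movie, tracks, intensity)
    res$mean_intensity <- vapply(res$track_id, function(tid)
      mean(means$value[means$track_id == tid]), double(1))
  }
  rownames(res) <- NULL
  res
}

track_region_means <- function(movie, tracks, intensity) {
  out <- lapply(sort(unique(tracks$frame)), function(t) {
    m <- frame_matrix(movie, t)
    mm <- intensity[t + 1L, , , drop = TRUE]
    if (!is.matrix(mm)) mm <- matrix(mm, nrow(m), ncol(m))
    sub <- tracks[tracks$frame == t, , drop = FALSE]
    vals <- vapply(sub$label, function(L) mean(mm[m == L]), double(1))
    data.frame(track_id = sub$track_id, frame = t, value = vals)
  })
  do.call(rbind, out)
}

#' Classify tracks into a group by intensity
#'
#' A track joins the group iff the chosen statistic of its per-frame mean
#' region intensity satisfies the threshold: `direction = "above"` keeps
#' `stat >= threshold` (ties resolve to "above"), `"below"` keeps
#' `stat < threshold`, so the two directions partition the tracks.
#'
#' @param movie a [label_movie()].
#' @param tracks a track table.
#' @param intensity `T x Y x X` intensity array.
#' @param stat `"mean"`, `"max"` or `"min"` over the track.
#' @param threshold intensity threshold.
#' @param direction `"above"` or `"below"`.
#' @param group_name name of the group (default `"group"`).
#' @return a data frame `track_id`, `stat_value`, `in_group`, `group`.
#' @export
group_from_track_intensity <- function(movie, tracks, intensity,
                                       stat = c("mean", "max", "min"),
                                       threshold,
                                       direction = c("above", "below"),
                                       group_name = "group") {
  stat <- match.arg(stat); direction <- match.arg(direction)
  if (!nrow(tracks)) stop_usage("empty track table")
  means <- track_region_means(movie, tracks, intensity)
  f <- factor(means$track_id)
  sfun <- switch(stat, mean = mean, max = max, min = min)
  sv <- tapply(means$value, f, sfun)
  ids <- as.integer(levels(f))
  inside <- if (direction == "above") sv >= threshold else sv < threshold
  data.frame(track_id = ids, stat_value = as.numeric(sv),
             in_group = as.logical(inside),
             group = ifelse(inside, group_name, "none"))
}

#' Temporal mean and confidence band of a feature
#'
#' Per frame (and per group if requested): `n`, `mean`, and the 0.95
#' normal-approximation confidence half-width `1.96 * sd / sqrt(n)` (`NA`
#' when `n < 2`).
#'
#' @param rows a cell-feature table ([cell_features()]).
#' @param feature feature column to aggregate.
#' @param by_group split by the `group` column.
#' @return a data frame `frame` (, `group`), `n`, `mean`, `ci`.
#' @export
temporal_table <- function(rows, feature, by_group = FALSE) {
  if (!feature %in% names(rows)) stop_usage("unknown feature: ", feature)
  key <- if (by_group) {
    if (!"group" %in% names(rows)) stop_usage("no 'group' column in rows")
    interaction(rows$frame, rows$group, drop = TRUE)
  } else factor(rows$frame)
  v <- rows[[feature]]
  n <- as.integer(tapply(v, key, length))
  mu <- as.numeric(tapply(v, key, mean))
  sdv <- as.numeric(tapply(v, key, sd))
  ci <- ifelse(n >= 2, 1.96 * sdv / sqrt(n), NA_real_)
  out <- data.frame(frame = as.integer(tapply(rows$frame, key, `[`, 1)))
  if (by_group) out$group <- as.character(tapply(as.character(rows$group),
                                                 key, `[`, 1))
  out$n <- n; out$mean <- mu; out$ci <- ci
  out[order(out$frame), , drop = FALSE]
}

#' Export a per-frame feature heatmap as a plain-text PPM image
#'
#' Each cell is filled with a colour mapped from its feature value
#' (blue-to-yellow ramp), background black: the headless analogue of the
#' in-GUI coloured temporal maps.
#'
#' @param movie a [label_movie()].
#' @param features a cell-feature table for `frame`.
#' @param feature feature column to map.
#' @param frame 0-based frame.
#' @param path output `.ppm` file (plain-text P3 format).
#' @export
export_feature_map <- function(movie, features, feature, frame, path) {
  m <- frame_matrix(movie, frame)
  sub <- features[features$frame == frame, , drop = FALSE]
  v <- sub[[feature]]
  rng <- range(v, finite = TRUE)
  z <- if (diff(rng) == 0) rep(0.5, length(v)) else (v - rng[1]) / diff(rng)
  ramp <- grDevices::colorRamp(c("#30123b", "#2a9d8f", "#e9c46a"))
  cols <- round(ramp(z))
  lut <- matrix(0L, max(sub$label) + 1L, 3)
  lut[sub$label + 1L, ] <- cols
  h <- nrow(m); w <- ncol(m)
  rgb <- matrix(0L, h, 3 * w)
  for (ch in 1:3) {
    chan <- matrix(0L, h, w)
    nz <- m > 0
    chan[nz] <- lut[m[nz] + 1L, ch]
    rgb[, seq(ch, 3 * w, by = 3)] <- chan
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  write(t(rgb), con, ncolumns = 12)
  invisible(path)
}
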