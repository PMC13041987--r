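#' Label movie container
#'
#' A label movie is a `T x Y x X` integer array in which every pixel carries
#' the id of the cell covering it and 0 marks background (or the 1-pixel
#' junction skeleton in "junction-gap" movies). Within one frame a nonzero
#' label must occupy exactly one 4-connected region; in a confluent movie
#' every interior background pixel must lie on a junction between at least
#' two cells.
#'
#' Two on-pixel representations are supported transparently: "dense" movies
#' where neighbouring cells share an edge with no background in between, and
#' "junction-gap" movies where cells are separated by a 1-pixel background
#' skeleton. All operations accept both; [skeletonize_frame()] is the
#' canonical bridge between them.
#'
#' @param data integer array, either `Y x X` (a single frame, promoted to
#'   `T = 1`) or `T x Y x X`.
#' @param pixel_size physical side of one pixel (micrometres per pixel).
#' @param frame_interval time between frames (minutes).
#' @return an object of class `label_movie` with fields `data`, `pixel_size`,
#'   `frame_interval`.
#' @export
label_movie <- function(data, pixel_size = 1.0, frame_interval = 1.0) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_data("label movie data must be a T x Y x X array (got ",
              length(dim(data)), " dimensions)")
  if (is.double(data)) {
    if (any(data != round(data)))
      stop_data("label movie must hold integer labels, found fractional values")
    storage.mode(data) <- "integer"
  }
  if (!is.integer(data)) stop_data("label movie must have integer storage")
  if (anyNA(data) || any(data < 0L))
    stop_data("label movie must be non-negative and free of NA")
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "label_movie")
}

#' @export
print.label_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("label_movie: %d frame(s) of %d x %d px, %d labels, %s\n",
              d[1], d[2], d[3], length(setdiff(unique(as.vector(x$data)), 0L)),
              if (movie_is_dense(x)) "dense" else "junction-gap"))
  invisible(x)
}

n_frames <- function(movie) dim(movie$data)[1]

# Y x X integer matrix of frame `frame` (0-based).
frame_matrix <- function(movie, frame) {
  Tn <- n_frames(movie)
  if (frame < 0 || frame >= Tn)
    stop_usage("frame ", frame, " out of range [0, ", Tn - 1, "]")
  m <- movie$data[frame + 1L, , , drop = TRUE]
  if (!is.matrix(m)) m <- matrix(m, dim(movie$data)[2], dim(movie$data)[3])
  m
}

set_frame_matrix <- function(movie, frame, m) {
  movie$data[frame + 1L, , ] <- m
  movie
}

# TRUE when no frame has interior background: the dense representation.
movie_is_dense <- function(movie) !any(movie$data == 0L)

#' Validate a label movie
#'
#' Checks the structural invariants: integer non-negative pixels, one
#' 4-connected region per (frame, label), and — in confluent mode — that
#' every interior background pixel lies on a junction (its 8-neighbourhood
#' holds at least two distinct labels) or next to the image border.
#'
#' @param movie a [label_movie()].
#' @param confluent enforce the confluence invariant (default `TRUE`).
#' @return a data frame with columns `frame`, `label`, `kind`, `n_pixels`,
#'   `detail`; zero rows iff the movie is valid.
#' @export
validate_movie <- function(movie, confluent = TRUE) {
  stopifnot(inherits(movie, "label_movie"))
  rep_rows <- list()
  d <- dim(movie$data)
  for (t in seq_len(d[1]) - 1L) {
    m <- frame_matrix(movie, t)
    labs <- setdiff(unique(as.vector(m)), 0L)
    if (length(labs)) {
      comp <- cpp_components4(m)
      nz <- m != 0L
      per_label <- tapply(comp[nz], m[nz], function(v) length(unique(v)))
      bad <- as.integer(names(per_label)[per_label > 1L])
      for (b in bad)
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          frame = t, label = b, kind = "split_label",
          n_pixels = sum(m == b),
          detail = sprintf("label %d occupies %d disconnected regions", b,
                           per_label[[as.character(b)]]))
    }
    if (confluent) {
      bg <- m == 0L
      if (any(bg)) {
        band <- cpp_junction_band(m)
        h <- nrow(m); w <- ncol(m)
        ry <- row(m) - 1L; rx <- col(m) - 1L
        interior <- ry > 1L & ry < h - 2L & rx > 1L & rx < w - 2L
        viol <- bg & !band & interior
        if (any(viol)) {
          ys <- ry[viol]; xs <- rx[viol]
          rep_rows[[length(rep_rows) + 1L]] <- data.frame(
            frame = t, label = NA_integer_, kind = "confluence",
            n_pixels = sum(viol),
            detail = sprintf(
              "%d interior background pixels off the junction skeleton, bbox y[%d,%d] x[%d,%d]",
              sum(viol), min(ys), max(ys), min(xs), max(xs)))
        }
      }
    }
  }
  if (!length(rep_rows))
    return(data.frame(frame = integer(), label = integer(), kind = character(),
                      n_pixels = integer(), detail = character()))
  do.call(rbind, rep_rows)
}

#' Per-cell geometry of one frame
#'
#' @param movie a [label_movie()].
#' @param frame 0-based frame index.
#' @return a data frame with one row per nonzero label present in the frame:
#'   `frame`, `label`, `area` (pixels), `y`, `x` (centroid, 0-based pixel
#'   coordinates), `ymin`, `xmin`, `ymax`, `xmax`, `touches_border`.
#' @export
region_table <- function(movie, frame) {
  m <- frame_matrix(movie, frame)
  region_table_matrix(m, frame)
}

region_table_matrix <- function(m, frame) {
  h <- nrow(m); w <- ncol(m)
  idx <- which(m != 0L)
  if (!length(idx))
    return(data.frame(frame = integer(), label = integer(), area = integer(),
                      y = double(), x = double(), ymin = integer(),
                      xmin = integer(), ymax = integer(), xmax = integer(),
                      touches_border = logical()))
  lab <- m[idx]
  yy <- (idx - 1L) %% h          # 0-based row
  xx <- (idx - 1L) %/% h         # 0-based column
  f <- factor(lab)
  area <- as.integer(tapply(lab, f, length))
  cy <- as.numeric(tapply(yy, f, mean))
  cx <- as.numeric(tapply(xx, f, mean))
  ymin <- as.integer(tapply(yy, f, min)); ymax <- as.integer(tapply(yy, f, max))
  xmin <- as.integer(tapply(xx, f, min)); xmax <- as.integer(tapply(xx, f, max))
  out <- data.frame(frame = frame, label = as.integer(levels(f)), area = area,
                    y = cy, x = cx, ymin = ymin, xmin = xmin, ymax = ymax,
                    xmax = xmax,
                    touches_border = ymin == 0L | xmin == 0L |
                      ymax == h - 1L | xmax == w - 1L)
  out[order(out$label), , drop = FALSE]
}

#' Junction skeleton of one frame
#'
#' A pixel belongs to the raw junction band when its 3x3 neighbourhood
#' (including itself) contains at least two distinct nonzero labels; the band
#' is then thinned to 1-pixel width. For junction-gap movies the band already
#' is the stored background skeleton; for dense movies it is the two-pixel
#' boundary band, reduced to a single line. Deterministic for fixed input.
#'
#' @inheritParams region_table
#' @return a logical `Y x X` mask.
#' @export
skeletonize_frame <- function(movie, frame) {
  m <- frame_matrix(movie, frame)
  cpp_thin(cpp_junction_band(m))
}

#' Cell adjacency graph of one frame
#'
#' Two labels are neighbours when their regions come within 2 pixels
#' (Chebyshev distance), which bridges the 1-pixel junction gap so that the
#' neighbour count ("NbNeighbor") is identical across the dense and
#' junction-gap representations.
#'
#' @inheritParams region_table
#' @param reach adjacency distance in pixels (default 2).
#' @return a data frame of unordered neighbour pairs `a < b` with a
#'   shared-boundary-length proxy `contact` (close pixel-pair count).
#' @export
neighbor_graph <- function(movie, frame, reach = 2L) {
  m <- frame_matrix(movie, frame)
  cpp_adjacency(m, as.integer(reach))
}

# Degree (NbNeighbor) of every label present in the frame, named vector.
neighbor_degree <- function(adj, labels) {
  deg <- setNames(integer(length(labels)), labels)
  if (nrow(adj)) {
    tab <- table(factor(c(adj$a, adj$b), levels = labels))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}
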