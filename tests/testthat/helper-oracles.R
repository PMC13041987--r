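# Independent oracles and tiny fixture builders. Everything here is written
# against the specification of each operation, not against the package's
# implementation path.

# movie from a list of Y x X integer matrices
movie_from_frames <- function(...) {
  frames <- list(...)
  if (length(frames) == 1L && is.list(frames[[1]]) && !is.matrix(frames[[1]]))
    frames <- frames[[1]]
  arr <- array(0L, dim = c(length(frames), nrow(frames[[1]]),
                           ncol(frames[[1]])))
  for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
  label_movie(arr)
}

# brute-force assignment oracle: minimise matched link costs plus the
# no-link charge D^2 per unmatched region, by exhaustive enumeration
oracle_assignment_cost <- function(cost, D2) {
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  recurse <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) {
      total <- acc + D2 * sum(!used)       # unmatched columns
      if (total < best) best <<- total
      return()
    }
    recurse(i + 1L, used, acc + D2)        # row i unmatched
    for (j in which(!used)) {
      if (is.finite(cost[i, j]))
        recurse(i + 1L, `[<-`(used, j, TRUE), acc + cost[i, j])
    }
  }
  recurse(1L, rep(FALSE, m), 0)
  best
}

# 3x3-scan oracle for the raw junction band: pixel on iff its neighbourhood
# (including itself) holds >= 2 distinct nonzero labels
oracle_junction_band <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (y in 1:h) for (x in 1:w) {
    ys <- max(1, y - 1):min(h, y + 1)
    xs <- max(1, x - 1):min(w, x + 1)
    vals <- setdiff(unique(as.vector(m[ys, xs])), 0L)
    out[y, x] <- length(vals) >= 2L
  }
  out
}

# O(L^2) dilation-overlap oracle for adjacency within Chebyshev `reach`
oracle_adjacency <- function(m, reach = 2L) {
  labs <- setdiff(sort(unique(as.vector(m))), 0L)
  dil <- function(mask, r) {
    h <- nrow(mask); w <- ncol(mask)
    out <- matrix(FALSE, h, w)
    for (y in 1:h) for (x in 1:w) if (mask[y, x]) {
      ys <- max(1, y - r):min(h, y + r)
      xs <- max(1, x - r):min(w, x + r)
      out[ys, xs] <- TRUE
    }
    out
  }
  pairs <- NULL
  for (a_i in seq_along(labs)) for (b_i in seq_along(labs)) {
    if (a_i >= b_i) next
    a <- labs[a_i]; b <- labs[b_i]
    if (any(dil(m == a, reach) & m == b))
      pairs <- rbind(pairs, data.frame(a = a, b = b))
  }
  pairs
}

# flood fill (4-connectivity) used to find background holes independently
oracle_flood_background <- function(m, start) {
  h <- nrow(m); w <- ncol(m)
  seen <- matrix(FALSE, h, w)
  stack <- list(start)
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    y <- p[1]; x <- p[2]
    if (y < 1 || y > h || x < 1 || x > w || seen[y, x] || m[y, x] != 0L) next
    seen[y, x] <- TRUE
    stack <- c(stack, list(c(y - 1, x), c(y + 1, x), c(y, x - 1), c(y, x + 1)))
  }
  seen
}

# canonical form of a track partition: sorted per-track sets of
# "frame:label" keys, id-agnostic
canonical_partition <- function(tracks) {
  sp <- split(paste(tracks$frame, tracks$label), tracks$track_id)
  unname(sort(vapply(sp, function(v) paste(sort(v), collapse = "|"), "")))
}

# a 5-frame movie of two static side-by-side cells
static_two_cell_movie <- function(n_frames = 5) {
  m <- matrix(0L, 8, 10)
  m[2:7, 2:5] <- 1L
  m[2:7, 6:9] <- 2L
  movie_from_frames(replicate(n_frames, m, simplify = FALSE))
}

# hand-built track table
track_table <- function(...) {
  df <- data.frame(...)
  if (!"parent_track" %in% names(df)) df$parent_track <- 0L
  if (!"area" %in% names(df)) df$area <- 100L
  df
}
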