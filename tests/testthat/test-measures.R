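test_that("area and shape index match closed forms for a square", {
  m <- matrix(0L, 20, 20)
  m[6:15, 6:15] <- 1L
  cf <- cell_features(movie_from_frames(m))
  expect_equal(cf$area, 100L)
  expect_equal(cf$shape_index, 4.0, tolerance = 0.05)      # 40 / sqrt(100)
  expect_equal(cf$perimeter, 40, tolerance = 0.05 * 40)
})

test_that("shape index approaches the disk and hexagon closed forms", {
  # digitised disk, radius 10
  yy <- row(matrix(0, 41, 41)) - 21; xx <- col(matrix(0, 41, 41)) - 21
  disk <- matrix(0L, 41, 41); disk[yy^2 + xx^2 <= 100] <- 1L
  cf <- cell_features(movie_from_frames(disk))
  expect_equal(cf$shape_index, 2 * sqrt(pi), tolerance = 0.05)
  # shape index is bounded below by the disk value
  expect_gte(cf$shape_index, 2 * sqrt(pi) * 0.999)

  # regular hexagon of circumradius 15: shape index 6 / sqrt(3*sqrt(3)/2)
  ang <- (0:5) * pi / 3
  hy <- 25 + 15 * sin(ang); hx <- 25 + 15 * cos(ang)
  hexm <- matrix(0L, 50, 50)
  for (y in 1:50) for (x in 1:50) {
    inside <- TRUE
    for (k in 1:6) {
      k2 <- k %% 6 + 1
      cr <- (hx[k2] - hx[k]) * (y - hy[k]) - (hy[k2] - hy[k]) * (x - hx[k])
      if (cr < 0) { inside <- FALSE; break }
    }
    if (inside) hexm[y, x] <- 1L
  }
  cf <- cell_features(movie_from_frames(hexm))
  hex_si <- 6 / sqrt(3 * sqrt(3) / 2)        # ~3.722
  expect_equal(cf$shape_index, hex_si, tolerance = 0.05)
})

test_that("NbNeighbor counts the adjacency ring; orientation follows the long axis", {
  sim <- get_small_sim(1)
  cf <- cell_features(sim$movie, frames = 0,
                      features = c("area", "NbNeighbor", "neighbors"))
  g <- neighbor_graph(sim$movie, 0)
  deg <- tissuecure:::neighbor_degree(g, cf$label)
  expect_equal(cf$NbNeighbor, unname(as.integer(deg)))
  expect_equal(lengths(cf$neighbors), cf$NbNeighbor)

  wide <- matrix(0L, 12, 24); wide[5:8, 3:22] <- 1L
  tall <- matrix(0L, 24, 12); tall[3:22, 5:8] <- 1L
  expect_equal(cell_features(movie_from_frames(wide),
                             features = "orientation")$orientation, 0)
  expect_equal(abs(cell_features(movie_from_frames(tall),
                                 features = "orientation")$orientation),
               pi / 2)
  expect_error(cell_features(sim$movie, features = "sparkle"), "unknown")
})

test_that("constant intensity yields equal junctional and cytoplasmic means", {
  m <- matrix(0L, 16, 16); m[2:15, 2:8] <- 1L; m[2:15, 9:15] <- 2L
  intens <- array(0.37, c(1, 16, 16))
  cf <- cell_features(movie_from_frames(m), intensity = intens)
  expect_equal(cf$cytoplasmic_intensity, c(0.37, 0.37))
  expect_equal(cf$junctional_intensity, c(0.37, 0.37))
  expect_error(cell_features(movie_from_frames(m),
                             features = "junctional_intensity"),
               "intensity")
})

test_that("track features match the worked displacement examples", {
  tr <- data.frame(track_id = rep(1:3, each = 3), frame = rep(0:2, 3),
                   label = rep(1:3, each = 3),
                   y = c(0, 0, 0, 0, 0, 0, 0, 3, 3),
                   x = c(0, 3, 6, 0, 3, 0, 0, 4, 9),
                   area = 10L, parent_track = 0L)
  tf <- track_features(tr)
  expect_equal(tf$duration, c(3, 3, 3))
  expect_equal(tf$avg_speed, c(3, 3, 5))
  expect_equal(tf$straightness, c(1, 0, sqrt(90) / 10))
})

test_that("straightness lies in [0,1], exactly 1 only for monotone collinear motion", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    tr <- data.frame(track_id = 1L, frame = seq_len(n) - 1L, label = 1L,
                     y = cumsum(rnorm(n)), x = cumsum(rnorm(n)),
                     area = 1L, parent_track = 0L)
    s <- track_features(tr)$straightness
    expect_gte(s, 0); expect_lte(s, 1 + 1e-12)
  }
})

test_that("group_from_track_intensity partitions tracks at the threshold", {
  sim <- get_small_sim(1)
  tracks <- sim$tracks
  dims <- dim(sim$movie$data)
  intens <- array(0.2, dims)
  # paint one cell's region bright in every frame
  bright <- tracks$track_id[1]
  for (t in unique(tracks$frame)) {
    m <- sim$movie$data[t + 1, , ]
    lay <- intens[t + 1, , ]
    lay[m == tracks$label[tracks$track_id == bright &
                            tracks$frame == t][1]] <- 0.9
    intens[t + 1, , ] <- lay
  }
  above <- group_from_track_intensity(sim$movie, tracks, intens, "mean",
                                      0.5, "above", "SO")
  below <- group_from_track_intensity(sim$movie, tracks, intens, "mean",
                                      0.5, "below", "rest")
  expect_equal(above$track_id[above$in_group], bright)
  expect_equal(sort(c(above$track_id[above$in_group],
                      below$track_id[below$in_group])),
               sort(above$track_id))
  expect_length(intersect(above$track_id[above$in_group],
                          below$track_id[below$in_group]), 0)
  # threshold below the global minimum puts everyone in the group
  all_in <- group_from_track_intensity(sim$movie, tracks, intens, "mean",
                                       0, "above", "all")
  expect_true(all(all_in$in_group))
})

test_that("temporal_table reports n, mean and a 0.95 normal CI", {
  rows <- data.frame(frame = rep(0:2, each = 4), label = rep(1:4, 3),
                     area = rep(50, 12), group = rep(c("a", "a", "b", "b"), 3))
  tt <- temporal_table(rows, "area")
  expect_equal(tt$mean, rep(50, 3))
  expect_equal(tt$ci, rep(0, 3))
  expect_equal(tt$n, rep(4L, 3))

  rows$area <- rows$area + rep(c(0, 0, 100, 100), 3)
  tg <- temporal_table(rows, "area", by_group = TRUE)
  expect_equal(sort(unique(tg$group)), c("a", "b"))
  expect_true(all(tg$mean[tg$group == "b"] > tg$mean[tg$group == "a"]))
  # n < 2 gives a missing CI
  single <- temporal_table(rows[rows$label == 1, ], "area")
  expect_true(all(is.na(single$ci)))
  expect_error(temporal_table(rows, "volume"), "unknown")
})

test_that("area totals per frame are conserved across the feature table", {
  sim <- get_small_sim(1)
  cf <- cell_features(sim$movie, frames = 0:2, features = "area")
  for (t in 0:2)
    expect_equal(sum(cf$area[cf$frame == t]), sum(sim$movie$data[t + 1, , ] > 0))
})

test_that("feature heatmap export writes a valid plain PPM", {
  sim <- get_small_sim(1)
  cf <- cell_features(sim$movie, frames = 0, features = "area")
  path <- tempfile(fileext = ".ppm")
  export_feature_map(sim$movie, cf, "area", 0, path)
  lines <- readLines(path, n = 3)
  expect_equal(lines[1], "P3")
  expect_equal(strsplit(lines[2], " ")[[1]],
               as.character(dim(sim$movie$data)[c(3, 2)]))
})
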