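test_that("label_movie validates shape and integer content", {
  expect_s3_class(label_movie(matrix(1L, 2, 2)), "label_movie")
  expect_equal(n_frames(label_movie(matrix(1L, 2, 2))), 1)   # T = 1 promote
  expect_error(label_movie(array(1L, dim = c(2, 2, 2, 2))), "T x Y x X")
  expect_error(label_movie(matrix(1.5, 2, 2)), "integer")
  expect_error(label_movie(matrix(-1L, 2, 2)), "non-negative")
})

test_that("validate_movie accepts the smallest confluent tiling and flags violations", {
  mv <- movie_from_frames(matrix(c(1L, 2L, 1L, 2L), 2, 2))
  expect_equal(nrow(validate_movie(mv)), 0)

  # label 3 as two disconnected blobs
  m <- matrix(c(3L, 1L, 3L, 3L, 1L, 3L), 2, 3)
  m <- matrix(0L, 4, 6)
  m[1:4, 1:2] <- 3L
  m[1:4, 3:4] <- 1L
  m[1:4, 5:6] <- 3L
  rep <- validate_movie(movie_from_frames(m))
  expect_true(any(rep$kind == "split_label" & rep$frame == 0 & rep$label == 3))

  # 3x3 interior background hole: compare against the flood-fill oracle
  m <- matrix(1L, 12, 12)
  m[5:7, 5:7] <- 0L
  hole <- oracle_flood_background(m, c(6, 6))
  rep <- validate_movie(movie_from_frames(m), confluent = TRUE)
  conf <- rep[rep$kind == "confluence", ]
  expect_equal(nrow(conf), 1)
  expect_equal(conf$n_pixels, sum(hole))
  # disabling confluence hides only that class of violation
  expect_equal(nrow(validate_movie(movie_from_frames(m), confluent = FALSE)), 0)
})

test_that("region_table matches hand geometry and conserves pixel counts", {
  mv <- movie_from_frames(matrix(c(1L, 2L, 1L, 2L), 2, 2))
  rt <- region_table(mv, 0)
  expect_equal(rt$label, c(1L, 2L))
  expect_equal(rt$area, c(2L, 2L))
  expect_equal(rt$y, c(0, 1))          # row centroids, 0-based
  expect_equal(rt$x, c(0.5, 0.5))

  expect_equal(nrow(region_table(movie_from_frames(matrix(0L, 4, 4)), 0)), 0)
  expect_error(region_table(mv, 5), "out of range")

  sim <- get_small_sim(1)
  rt <- region_table(sim$movie, 3)
  expect_equal(sum(rt$area), sum(sim$movie$data[4, , ] > 0))
})

test_that("region_table areas are invariant under label permutation", {
  sim <- get_small_sim(1)
  m <- sim$movie$data[1, , ]
  labs <- sort(unique(as.vector(m[m > 0])))
  perm <- setNames(sample(labs), labs)
  m2 <- m
  m2[m > 0] <- perm[as.character(m[m > 0])]
  a1 <- sort(region_table(movie_from_frames(m), 0)$area)
  a2 <- sort(region_table(movie_from_frames(m2), 0)$area)
  expect_identical(a1, a2)
})

test_that("skeletonize_frame produces the thinned junction band", {
  # one cell filling the image: no junctions
  expect_equal(sum(skeletonize_frame(movie_from_frames(matrix(1L, 8, 8)), 0)), 0)

  # junction-gap: two cells split by a 1-px background line -> exactly it
  m <- matrix(0L, 8, 8)
  m[, 1:3] <- 1L; m[, 5:8] <- 2L
  sk <- skeletonize_frame(movie_from_frames(m), 0)
  expect_identical(sk, col(m) == 4)

  # dense: the two-pixel boundary band thins to a single vertical line
  m2 <- matrix(0L, 8, 8)
  m2[, 1:4] <- 1L; m2[, 5:8] <- 2L
  sk2 <- skeletonize_frame(movie_from_frames(m2), 0)
  expect_true(all(which(sk2, arr.ind = TRUE)[, 2] %in% 4:5))
  expect_true(sum(sk2) >= 6 && sum(sk2) <= 10)

  # synthetic frame: the pre-thinning band equals the brute-force 3x3 scan,
  # and the skeleton is 1 pixel wide (no full 2x2 block survives)
  sim <- get_small_sim(1)
  m <- sim$movie$data[1, , ]
  band <- tissuecure:::cpp_junction_band(m)
  expect_identical(matrix(as.logical(band), nrow(m)), oracle_junction_band(m))
  sk <- skeletonize_frame(sim$movie, 0)
  blocks <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
    sk[-nrow(sk), -1] & sk[-1, -1]
  expect_equal(sum(blocks), 0)
})

test_that("skeleton is invariant under label permutation", {
  sim <- get_small_sim(1)
  m <- sim$movie$data[2, , ]
  labs <- sort(unique(as.vector(m[m > 0])))
  perm <- setNames(rev(labs), labs)
  m2 <- m
  m2[m > 0] <- perm[as.character(m[m > 0])]
  expect_identical(skeletonize_frame(movie_from_frames(m), 0),
                   skeletonize_frame(movie_from_frames(m2), 0))
})

test_that("neighbor_graph matches the dilation oracle and hand cases", {
  mv <- movie_from_frames(matrix(c(1L, 2L, 1L, 2L), 2, 2))
  g <- neighbor_graph(mv, 0)
  expect_equal(nrow(g), 1)
  expect_equal(c(g$a, g$b), c(1L, 2L))

  sim <- get_small_sim(1)
  m <- sim$movie$data[1, , ]
  g <- neighbor_graph(sim$movie, 0)
  orc <- oracle_adjacency(m, 2L)
  got <- paste(g$a, g$b)
  want <- paste(orc$a, orc$b)
  expect_setequal(got, want)
})

test_that("an interior cell of the tissue has its full ring of neighbours", {
  sim <- get_small_sim(2)
  m <- sim$movie$data[1, , ]
  rt <- region_table(sim$movie, 0)
  g <- neighbor_graph(sim$movie, 0)
  deg <- tissuecure:::neighbor_degree(g, rt$label)
  interior <- rt$label[!rt$touches_border]
  expect_true(all(deg[as.character(interior)] >= 4))
})
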