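# a 10x10 two-cell frame with tracks, for operator micro-tests
two_cell_state <- function(n_frames = 3) {
  mv <- static_two_cell_movie(n_frames)
  list(movie = mv, tracks = build_tracks(mv))
}

test_that("merge unions adjacent cells, keeps the lower id, refuses distant pairs", {
  # dense frame: union is exactly the two regions
  md <- matrix(0L, 8, 10); md[, 1:5] <- 1L; md[, 6:10] <- 2L
  mvd <- movie_from_frames(md, md, md)
  trd <- build_tracks(mvd)
  res <- merge_cells(mvd, trd, 1, 2, 1)
  m <- res$movie$data[2, , ]
  expect_false(any(m == 2))
  expect_equal(sum(m == 1), sum(md > 0))
  # cell count at the frame dropped by one
  expect_equal(length(setdiff(unique(as.vector(m)), 0L)), 1)

  # distant labels: build a 3-cell frame where 1 and 3 do not touch
  m3 <- matrix(0L, 6, 12)
  m3[, 1:4] <- 1L; m3[, 5:8] <- 2L; m3[, 9:12] <- 3L
  mv3 <- movie_from_frames(m3)
  tr3 <- build_tracks(mv3)
  expect_error(merge_cells(mv3, tr3, 0, 1, 3), "not adjacent")
  expect_error(merge_cells(mv3, tr3, 0, 2, 2), "itself")
})

test_that("merge absorbs the junction gap between cells in gap representation", {
  m <- matrix(0L, 7, 9)
  m[2:6, 2:4] <- 1L
  m[2:6, 6:8] <- 2L      # column 5 is a junction gap
  mv <- movie_from_frames(m)
  tr <- build_tracks(mv)
  res <- merge_cells(mv, tr, 0, 1, 2, relink = FALSE)
  a_before <- sum(m == 1); b_before <- sum(m == 2)
  absorbed <- sum(m == 0 & res$movie$data[1, , ] == 1)
  expect_equal(sum(res$movie$data[1, , ] == 1), a_before + b_before + absorbed)
  expect_gt(absorbed, 0)
})

test_that("split by symmetric seeds halves a rectangle; bad seeds error", {
  m <- matrix(0L, 6, 8)
  m[3:4, 3:6] <- 7L      # a 2x4 cell
  mv <- movie_from_frames(m)
  tr <- build_tracks(mv)
  res <- split_cell(mv, tr, 0, 7, rbind(c(2, 3), c(2, 4)))
  out <- res$movie$data[1, , ]
  labs <- setdiff(unique(as.vector(out)), 0L)
  expect_length(labs, 2)
  expect_equal(sort(as.integer(table(out[out > 0]))), c(4L, 4L))
  expect_equal(sum(out > 0), sum(m > 0))          # union preserved
  expect_equal(out[3:4, 3:4], matrix(7L, 2, 2))   # seed-1 part keeps label

  expect_error(split_cell(mv, tr, 0, 7, rbind(c(2, 3))), "at least 2")
  expect_error(split_cell(mv, tr, 0, 7, rbind(c(0, 0), c(2, 4))), "inside")
})

test_that("merge of a seeded split restores the original frame", {
  sim <- get_small_sim(1)
  tracks <- build_tracks(sim$movie)
  rt <- region_table(sim$movie, 4)
  lab <- rt$label[!rt$touches_border][which.max(rt$area[!rt$touches_border])]
  row <- rt[rt$label == lab, ]
  seeds <- rbind(c(row$y, row$x - 3), c(row$y, row$x + 3))
  sp <- split_cell(sim$movie, tracks, 4, lab, seeds)
  expect_length(sp$part_labels, 2)
  mg <- merge_cells(sp$movie, sp$tracks, 4, sp$part_labels[1],
                    sp$part_labels[2])
  expect_identical(mg$movie$data, sim$movie$data)
  expect_equal(nrow(validate_movie(mg$movie)), 0)
})

test_that("draw_junction splits a cell along a polyline and checks separation", {
  # dense frame: the path pixels are reassigned to the two sides
  m <- matrix(5L, 8, 8)
  mv <- movie_from_frames(m)
  tr <- build_tracks(mv)
  res <- draw_junction(mv, tr, 0, rbind(c(0, 4), c(7, 4)))
  out <- res$movie$data[1, , ]
  expect_length(setdiff(unique(as.vector(out)), 0L), 2)
  expect_equal(sum(out > 0), sum(m > 0))
  expect_equal(nrow(validate_movie(res$movie, confluent = FALSE)), 0)

  # junction-gap frame: the path becomes background skeleton
  mg <- matrix(0L, 9, 9)
  mg[2:8, 2:4] <- 1L; mg[2:8, 6:8] <- 2L
  mvg <- movie_from_frames(mg)
  trg <- build_tracks(mvg)
  resg <- draw_junction(mvg, trg, 0, rbind(c(1, 2), c(7, 2)))
  outg <- resg$movie$data[1, , ]
  expect_length(setdiff(unique(as.vector(outg)), 0L), 3)
  expect_equal(nrow(validate_movie(resg$movie)), 0)

  # a path ending mid-cell separates nothing
  expect_error(draw_junction(mv, tr, 0, rbind(c(0, 4), c(4, 4))),
               "does not separate")
})

test_that("remove_cell truncates and optionally repairs", {
  st <- two_cell_state(4)
  tid <- st$tracks$track_id[st$tracks$label == 2][1]
  res <- remove_cell(st$movie, st$tracks, 2, tid)
  expect_false(any(res$movie$data[3:4, , ] == 2))
  expect_true(any(res$movie$data[1:2, , ] == 2))
  expect_equal(max(res$tracks$frame[res$tracks$track_id == tid]), 1)
  expect_equal(nrow(validate_movie(res$movie, confluent = FALSE)), 0)

  res2 <- remove_cell(st$movie, st$tracks, 3, tid, repair = TRUE)
  m <- res2$movie$data[4, , ]
  expect_false(any(m == 2))
  expect_equal(sum(m == 1), sum(st$movie$data[4, , ] > 0))  # neighbour absorbed

  expect_error(remove_cell(st$movie, st$tracks, 0, 999), "unknown")
})

test_that("swap_tracks is an involution and id_a == id_b is a no-op", {
  sim <- get_small_sim(1)
  tracks <- sim$tracks
  g <- neighbor_graph(sim$movie, 8)
  a <- g$a[1]; b <- g$b[1]
  sw <- swap_tracks(sim$movie, tracks, 8, a, b)
  expect_false(identical(sw$movie$data, sim$movie$data))
  sw2 <- swap_tracks(sw$movie, sw$tracks, 8, a, b)
  expect_identical(sw2$movie$data, sim$movie$data)
  expect_equal(canonical_partition(sw2$tracks), canonical_partition(tracks))

  same <- swap_tracks(sim$movie, tracks, 8, a, a)
  expect_identical(same$movie$data, sim$movie$data)
  expect_error(swap_tracks(sim$movie, tracks, 8, a, 99999), "unknown")
})

test_that("set_track moves a tail into another track and guards collisions", {
  tr <- data.frame(track_id = c(1L, 1L, 1L, 2L, 2L),
                   frame = c(0L, 1L, 2L, 2L, 3L),
                   label = c(1L, 1L, 1L, 2L, 2L), y = 1, x = 1, area = 10L,
                   parent_track = 0L)
  mv <- label_movie(array(1L, c(4, 4, 4)))   # labels not track-coded here
  res <- set_track(mv, tr[tr$track_id == 1L | tr$frame == 3L, ], 3, 2, 1)
  expect_equal(sort(res$tracks$frame[res$tracks$track_id == 1]), 0:3)
  expect_error(set_track(mv, tr, 2, 1, 2), "already")
  expect_error(set_track(mv, tr, 9, 1, 2), "no rows")
})

test_that("fill_hole restores a dropped cell region exactly", {
  sim <- get_small_sim(1)
  tracks <- build_tracks(sim$movie)
  movie <- sim$movie
  rt <- region_table(movie, 6)
  lab <- rt$label[!rt$touches_border][1]
  m <- movie$data[7, , ]
  idx <- which(m == lab)
  m[idx] <- 0L
  movie$data[7, , ] <- m
  seedpix <- c((idx[1] - 1) %% nrow(m), (idx[1] - 1) %/% nrow(m))
  res <- fill_hole(movie, tracks, 6, seedpix, label = lab)
  expect_identical(res$movie$data, sim$movie$data)
  expect_error(fill_hole(res$movie, res$tracks, 6, seedpix, label = lab),
               "not on background")
})

test_that("apply_edit_script is ordered, partial on failure, identity when empty", {
  st <- two_cell_state()
  res <- apply_edit_script(st$movie, st$tracks, edit_script(list()))
  expect_identical(res$movie$data, st$movie$data)
  expect_true(is.na(res$failed_at))

  sc <- edit_script(list(
    list(op = "merge", frame = 0, label_a = 1, label_b = 2),
    list(op = "merge", frame = 1, label_a = 1, label_b = 2),
    list(op = "merge", frame = 2, label_a = 1, label_b = 777)))
  res <- apply_edit_script(st$movie, st$tracks, sc, stop_on_error = FALSE)
  expect_equal(res$failed_at, 3)
  expect_false(any(res$movie$data[1:2, , ] == 2))   # ops 1..2 applied
  expect_true(any(res$movie$data[3, , ] == 2))      # op 3 aborted

  err <- tryCatch(apply_edit_script(st$movie, st$tracks, sc),
                  error = function(e) e)
  expect_s3_class(err, "tc_script_error")
  expect_equal(err$position, 3)
})

test_that("operators preserve validity and cell-count bookkeeping", {
  sim <- get_small_sim(2)
  tracks <- build_tracks(sim$movie)
  count_at <- function(mv, t)
    length(setdiff(unique(as.vector(mv$data[t + 1, , ])), 0L))
  n0 <- count_at(sim$movie, 3)
  rt <- region_table(sim$movie, 3)
  lab <- rt$label[!rt$touches_border][which.max(rt$area[!rt$touches_border])]
  row <- rt[rt$label == lab, ]
  sp <- split_cell(sim$movie, tracks, 3, lab,
                   rbind(c(row$y, row$x - 3), c(row$y, row$x + 3)))
  expect_equal(count_at(sp$movie, 3), n0 + 1)
  expect_equal(nrow(validate_movie(sp$movie)), 0)
  mg <- merge_cells(sp$movie, sp$tracks, 3, sp$part_labels[1],
                    sp$part_labels[2])
  expect_equal(count_at(mg$movie, 3), n0)
  expect_equal(nrow(validate_movie(mg$movie)), 0)
  # the track partition property still holds after the edits
  expect_false(any(duplicated(paste(mg$tracks$frame, mg$tracks$label))))
})
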