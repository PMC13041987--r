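test_that("sim_params rejects unschedulable event loads", {
  expect_error(sim_params(n_frames = 8, n_divisions = 5, n_extrusions = 5),
               "schedule")
  expect_s3_class(sim_params(), "sim_params")
})

test_that("simulation is deterministic and structurally valid", {
  a <- simulate_epithelium(small_sim_params(4))
  b <- simulate_epithelium(small_sim_params(4))
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$events, b$events)
  expect_identical(a$intensity, b$intensity)

  expect_equal(nrow(validate_movie(a$movie)), 0)
  expect_equal(nrow(a$events), 2)
  # ground-truth tracks satisfy the partition property
  expect_false(any(duplicated(paste(a$tracks$frame, a$tracks$label))))
  expect_equal(nrow(a$tracks), sum(vapply(seq_len(n_frames(a$movie)) - 1L,
                                          function(t)
                                            nrow(region_table(a$movie, t)),
                                          0L)))
  # lineage edges recorded for the scheduled division
  div <- a$events[a$events$kind == "division", ]
  dg <- a$tracks[a$tracks$track_id %in% c(div$daughter1, div$daughter2), ]
  expect_true(all(dg$parent_track == div$parent_track))
})

test_that("a frozen tissue has constant frames and full-length tracks", {
  p <- sim_params(width = 90, height = 90, n_cells = 25, n_frames = 6,
                  drift_sigma = 0, n_divisions = 0, n_extrusions = 0,
                  seed = 2)
  sim <- simulate_epithelium(p)
  for (t in 1:5)
    expect_identical(sim$movie$data[t + 1, , ], sim$movie$data[1, , ])
  ext <- tissuecure:::track_extents(sim$tracks)
  expect_true(all(ext$n == 6))
  expect_equal(nrow(sim$events), 0)
})

test_that("a single-frame simulation is one tessellated frame", {
  p <- sim_params(width = 80, height = 80, n_cells = 20, n_frames = 1,
                  n_divisions = 0, n_extrusions = 0, seed = 3)
  sim <- simulate_epithelium(p)
  expect_equal(n_frames(sim$movie), 1)
  expect_equal(length(unique(as.vector(sim$movie$data))), 20)
  expect_equal(nrow(sim$events), 0)
})

test_that("zero corruption probabilities are the identity", {
  sim <- get_small_sim(1)
  cor <- corrupt_movie(sim$movie, sim$tracks,
                       corruption_params(0, 0, 0, 0, seed = 1))
  expect_identical(cor$movie$data, sim$movie$data)
  expect_equal(nrow(cor$log), 0)
  expect_length(cor$inverse, 0)
})

test_that("a forced split on a single-cell frame logs one invertible op", {
  mv <- movie_from_frames(matrix(1L, 12, 12))
  tr <- build_tracks(mv)
  cor <- corrupt_movie(mv, tr, corruption_params(p_split = 1, p_merge = 0,
                                                 p_dropout = 0, p_swap = 0,
                                                 seed = 2))
  expect_equal(nrow(cor$log), 1)
  expect_equal(cor$log$kind, "split")
  expect_equal(length(setdiff(unique(as.vector(cor$movie$data)), 0L)), 2)
  expect_length(cor$inverse, 1)
  expect_equal(cor$inverse[[1]]$op, "merge")
  res <- apply_edit_script(cor$movie, cor$tracks, cor$inverse)
  expect_identical(res$movie$data, mv$data)
})

test_that("corruption round trip is bit-exact across seeds (reduced scale)", {
  for (s in 1:6) {
    sim <- get_small_sim(s)
    cor <- corrupt_movie(sim$movie, sim$tracks,
                         corruption_params(p_split = 0.04, p_merge = 0.04,
                                           p_dropout = 0.04, p_swap = 0.04,
                                           seed = 50 + s),
                         events = sim$events)
    expect_gt(nrow(cor$log), 0)
    res <- apply_edit_script(cor$movie, cor$tracks, cor$inverse)
    expect_identical(res$movie$data, sim$movie$data)
    # the restored table still partitions the movie
    expect_false(any(duplicated(paste(res$tracks$frame, res$tracks$label))))
  }
})

test_that("corruption is deterministic in its own seed on a fixed tissue", {
  sim <- get_small_sim(2)
  c1 <- corrupt_movie(sim$movie, sim$tracks, corruption_params(seed = 9),
                      events = sim$events)
  c2 <- corrupt_movie(sim$movie, sim$tracks, corruption_params(seed = 9),
                      events = sim$events)
  c3 <- corrupt_movie(sim$movie, sim$tracks, corruption_params(seed = 10),
                      events = sim$events)
  expect_identical(c1$movie$data, c2$movie$data)
  expect_identical(c1$log, c2$log)
  expect_false(identical(c1$log, c3$log))
})

test_that("the probability-bump movie peaks at the scheduled events", {
  sim <- get_small_sim(3)
  prob <- event_probability_movie(sim$events, dim(sim$movie$data))
  expect_true(all(prob >= 0 & prob <= 1))
  for (k in seq_len(nrow(sim$events))) {
    ev <- sim$events[k, ]
    expect_gt(prob[ev$frame + 1, round(ev$y) + 1, round(ev$x) + 1], 0.9)
  }
})
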