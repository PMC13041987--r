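mk_track <- function(tid, frames, y, x, area = 100) {
  n <- length(frames)
  data.frame(track_id = tid, frame = frames,
             label = tid, y = rep_len(y, n), x = rep_len(x, n),
             area = rep_len(area, n),
             ymin = rep_len(y, n) - 4, xmin = rep_len(x, n) - 4,
             ymax = rep_len(y, n) + 4, xmax = rep_len(x, n) + 4,
             parent_track = 0L)
}

test_that("detect_divisions applies the end-plus-two-nearby-starts rule", {
  # hand-built: parent ends at (10,10) t=5; starters at (8,10), (12,10) t=6
  tr <- rbind(mk_track(1, 0:5, 10, 10, area = 200),
              mk_track(2, 6:9, 8, 10, area = 90),
              mk_track(3, 6:9, 12, 10, area = 90),
              mk_track(4, 0:9, 30, 30))
  ev <- detect_divisions(tr, event_params(div_radius = 6))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "division")
  expect_equal(ev$frame, 6)
  expect_equal(c(ev$y, ev$x), c(10, 10))      # middle of the daughters
  expect_equal(ev$parent_track, 1)
  expect_equal(c(ev$daughter1, ev$daughter2), c(2, 3))

  # one starter only: no division
  tr1 <- rbind(mk_track(1, 0:5, 10, 10, area = 200),
               mk_track(2, 6:9, 8, 10, area = 90),
               mk_track(4, 0:9, 30, 30))
  expect_equal(nrow(detect_divisions(tr1, event_params(div_radius = 6))), 0)

  # each starter consumed at most once: a second lonely end gets nothing
  tr2 <- rbind(tr, mk_track(5, 0:5, 11, 11, area = 200))
  ev2 <- detect_divisions(tr2, event_params(div_radius = 6))
  expect_lte(nrow(ev2), 1)
})

test_that("detect_extrusions requires a small interior terminal area", {
  tr <- rbind(mk_track(1, 0:6, 20, 20, area = c(rep(100, 5), 20, 6)),
              mk_track(2, 0:9, 40, 40, area = 100),
              mk_track(3, 0:6, 50, 50, area = 200),   # ends large: no event
              mk_track(4, 0:9, 60, 60, area = 100))
  attr(tr, "dims") <- c(10L, 80L, 80L)
  ev <- detect_extrusions(tr, params = event_params(extrusion_area_max = 10))
  expect_equal(ev$kind, "extrusion")
  expect_equal(ev$parent_track, 1)
  expect_equal(ev$frame, 6)
  expect_equal(c(ev$y, ev$x), c(20, 20))

  # a division parent is never an extrusion
  div <- data.frame(event_id = 1L, kind = "division", frame = 7L, y = 20,
                    x = 20, parent_track = 1L, daughter1 = 10L,
                    daughter2 = 11L)
  expect_equal(nrow(detect_extrusions(tr, div,
                                      event_params(extrusion_area_max = 10))),
               0)
})

test_that("detectors recover the scheduled events exactly on clean simulation", {
  sim <- get_small_sim(3)
  tr <- build_tracks(sim$movie)
  div <- detect_divisions(tr)
  ext <- detect_extrusions(tr, div)
  gt <- sim$events
  expect_equal(nrow(div), sum(gt$kind == "division"))
  expect_equal(nrow(ext), sum(gt$kind == "extrusion"))
  for (k in which(gt$kind == "division"))
    expect_true(any(div$frame == gt$frame[k] &
                      abs(div$y - gt$y[k]) < 1e-6 &
                      abs(div$x - gt$x[k]) < 1e-6))
  for (k in which(gt$kind == "extrusion"))
    expect_true(any(ext$frame == gt$frame[k] &
                      abs(ext$y - gt$y[k]) < 1e-6))
  # partition: no terminal both divides and extrudes
  expect_length(intersect(div$parent_track, ext$parent_track), 0)
})

test_that("probability filtering keeps all at 1, none at 0, and is monotone", {
  sim <- get_small_sim(3)
  tr <- build_tracks(sim$movie)
  div <- detect_divisions(tr)
  dims <- dim(sim$movie$data)
  expect_equal(nrow(filter_events_by_probability(div, array(1, dims))),
               nrow(div))
  expect_equal(nrow(filter_events_by_probability(div, array(0, dims))), 0)

  prob <- event_probability_movie(sim$events, dims)
  kept <- lapply(c(0.2, 0.5, 0.9), function(th)
    filter_events_by_probability(div, prob,
                                 event_params(prob_threshold = th))$event_id)
  expect_true(all(kept[[2]] %in% kept[[1]]))
  expect_true(all(kept[[3]] %in% kept[[2]]))
})

test_that("fate groups mark terminals and reject contradictory fates", {
  tr <- rbind(mk_track(1, 0:5, 10, 10), mk_track(2, 6:9, 8, 10),
              mk_track(3, 6:9, 12, 10), mk_track(4, 0:7, 30, 30),
              mk_track(5, 0:9, 50, 50))
  ev <- rbind(
    data.frame(event_id = 1L, kind = "division", frame = 6L, y = 10, x = 10,
               parent_track = 1L, daughter1 = 2L, daughter2 = 3L),
    data.frame(event_id = 2L, kind = "extrusion", frame = 7L, y = 30, x = 30,
               parent_track = 4L, daughter1 = NA_integer_,
               daughter2 = NA_integer_))
  fg <- fate_groups(tr, ev)
  expect_equal(fg$group[fg$track_id == 1], "Dividing")
  expect_equal(fg$group[fg$track_id == 4], "Extruding")
  expect_equal(fg$group[fg$track_id == 5], "none")

  bad <- rbind(ev, data.frame(event_id = 3L, kind = "extrusion", frame = 5L,
                              y = 10, x = 10, parent_track = 1L,
                              daughter1 = NA_integer_,
                              daughter2 = NA_integer_))
  expect_error(fate_groups(tr, bad), "both")
})

test_that("relative area to event is a ratio against the neighbour mean", {
  feats <- data.frame(frame = rep(0:2, each = 3),
                      label = rep(1:3, 3), track_id = rep(1:3, 3),
                      area = c(4, 2, 6, 4, 2, 6, 4, 2, 6))
  feats$neighbors <- rep(list(c(2L, 3L), c(1L, 3L), c(1L, 2L)), 3)
  ev <- data.frame(event_id = 1L, kind = "extrusion", frame = 2L, y = 0,
                   x = 0, parent_track = 1L, daughter1 = NA_integer_,
                   daughter2 = NA_integer_)
  ra <- relative_area_to_event(ev, feats)
  expect_equal(ra$t_rel, -2:0)
  expect_equal(ra$ratio, rep(1, 3))          # 4 / mean(2, 6) = 1

  # no neighbours at a frame: NA, not an error
  feats$neighbors[[1]] <- integer(0)
  ra <- relative_area_to_event(ev, feats)
  expect_true(is.na(ra$ratio[ra$t_rel == -2]))
  expect_error(relative_area_to_event(ev, feats[, names(feats) != "neighbors"]),
               "neighbors")
})
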