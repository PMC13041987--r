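#' Skeleton intersection-over-union of two movies
#'
#' Both movies are reduced to their binary junction-skeleton movies
#' ([skeletonize_frame()]) and the IoU is pooled over all frames as a single
#' ratio `|S_b & S_a| / |S_b | S_a|`. Two empty skeletons have IoU 1. Only
#' sensitive to segmentation (not track identity): skeletons are invariant
#' under label permutation.
#'
#' @param movie_before,movie_after [label_movie()]s of identical geometry.
#' @return a number in \[0, 1\].
#' @export
skeleton_iou <- function(movie_before, movie_after) {
  if (!identical(dim(movie_before$data), dim(movie_after$data)))
    stop_data("movies have different geometry")
  inter <- 0; uni <- 0
  for (t in seq_len(n_frames(movie_before)) - 1L) {
    sb <- skeletonize_frame(movie_before, t)
    sa <- skeletonize_frame(movie_after, t)
    inter <- inter + sum(sb & sa)
    uni <- uni + sum(sb | sa)
  }
  if (uni == 0) 1 else inter / uni
}

count_cells <- function(movie) {
  sum(vapply(seq_len(n_frames(movie)) - 1L, function(t) {
    m <- frame_matrix(movie, t)
    length(setdiff(unique(as.vector(m)), 0L))
  }, double(1)))
}

#' Segmentation cell-count error
#'
#' `(N_after - N_before) / N_after` where `N` is the total number of cell
#' objects over the whole movie regardless of track. Signed: positive when
#' the initial segmentation under-segmented, negative when it
#' over-segmented.
#'
#' @inheritParams skeleton_iou
#' @return a signed fraction.
#' @export
cell_nb_error <- function(movie_before, movie_after) {
  na <- count_cells(movie_after)
  if (na == 0) stop_data("after-movie contains no cells")
  nb <- count_cells(movie_before)
  (na - nb) / na
}

#' Track-duration error
#'
#' `(mean duration after - mean duration before) / mean duration after`,
#' durations in observed frames; the after tracks play the role of ground
#' truth.
#'
#' @param tracks_before,tracks_after track tables.
#' @return a signed fraction.
#' @export
length_track_error <- function(tracks_before, tracks_after) {
  if (!nrow(tracks_before) || !nrow(tracks_after))
    stop_data("empty track table")
  db <- mean(track_extents(tracks_before)$n)
  da <- mean(track_extents(tracks_after)$n)
  (da - db) / da
}

#' Mean cell-area error along tracks
#'
#' `(mean area after - mean area before) / mean area after`, the mean taken
#' over all (frame, label) observations along tracks.
#'
#' @param tracks_before,tracks_after track tables carrying an `area` column.
#' @return a signed fraction.
#' @export
area_track_error <- function(tracks_before, tracks_after) {
  if (!nrow(tracks_before) || !nrow(tracks_after))
    stop_data("empty track table")
  ab <- mean(tracks_before$area)
  aa <- mean(tracks_after$area)
  (aa - ab) / aa
}

#' Before/after curation-quality report
#'
#' The four curation metrics in one call: skeleton IoU, cell-count error,
#' track-duration error and track-area error. Track tables are rebuilt with
#' [build_tracks()] when not supplied. All four reach their perfect values
#' (1, 0, 0, 0) iff the movies agree up to a label permutation.
#'
#' @inheritParams skeleton_iou
#' @param tracks_before,tracks_after optional track tables.
#' @param params [tracking_params()] for the rebuilds.
#' @return a list `skeleton_iou`, `cell_nb_error`, `length_track_error`,
#'   `area_track_error`.
#' @export
curation_report <- function(movie_before, movie_after, tracks_before = NULL,
                            tracks_after = NULL,
                            params = tracking_params()) {
  if (is.null(tracks_before)) tracks_before <- build_tracks(movie_before, params)
  if (is.null(tracks_after)) tracks_after <- build_tracks(movie_after, params)
  list(skeleton_iou = skeleton_iou(movie_before, movie_after),
       cell_nb_error = cell_nb_error(movie_before, movie_after),
       length_track_error = length_track_error(tracks_before, tracks_after),
       area_track_error = area_track_error(tracks_before, tracks_after))
}
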