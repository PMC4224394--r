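#' Detection performance against ground truth
#'
#' Matches detections to true object positions frame by frame (greedy
#' nearest-pair matching within `match_radius_px`) and reports recall (matched
#' truths / truths) and precision (matched detections / detections).
#'
#' @param detections data.frame with `frame`, `x_px`, `y_px`.
#' @param truth a `ground_truth` (its `true_tracks` supplies positions).
#' @param match_radius_px matching radius in pixels (default 2).
#' @return List with `recall`, `precision`, `n_true`, `n_detected`,
#'   `n_matched`.
#' @export
detection_performance <- function(detections, truth, match_radius_px = 2) {
  tt <- truth$true_tracks
  det_by <- split(detections, detections$frame)
  true_by <- split(tt, tt$frame)
  n_true <- nrow(tt); n_det <- nrow(detections); n_match <- 0L
  for (f in names(true_by)) {
    tr <- true_by[[f]]
    de <- det_by[[f]]
    if (is.null(de) || nrow(de) == 0L) next
    n_match <- n_match + greedy_match_count(tr$x_px, tr$y_px,
                                            de$x_px, de$y_px, match_radius_px)
  }
  list(recall = if (n_true > 0L) n_match / n_true else NA_real_,
       precision = if (n_det > 0L) n_match / n_det else NA_real_,
       n_true = n_true, n_detected = n_det, n_matched = n_match)
}

# One-to-one matching by ascending pair distance within a radius.
greedy_match_count <- function(xa, ya, xb, yb, radius) {
  d2 <- outer(xa, xb, "-")^2 + outer(ya, yb, "-")^2
  d2[d2 > radius^2] <- NA
  n <- 0L
  while (any(is.finite(d2))) {
    k <- which.min(d2)
    i <- (k - 1L) %% nrow(d2) + 1L
    j <- (k - 1L) %/% nrow(d2) + 1L
    d2[i, ] <- NA
    d2[, j] <- NA
    n <- n + 1L
  }
  n
}

#' Tracking performance against ground truth
#'
#' Each detection in each track is assigned to the nearest true object of the
#' same frame within `match_radius_px`. A track's identity is its majority
#' assigned object; frames assigned to a different object than the track
#' majority are identity errors, and transitions between assigned objects
#' within a track are identity switches. A true object is *recovered* when
#' the frames covered by tracks of its identity (counting only correctly
#' assigned frames) amount to at least `coverage_min` of its frames. Brief
#' mismatches during close encounters of two objects (where detections merge)
#' cost coverage but do not void a whole track.
#'
#' @param tracks data.frame as returned by [build_tracks()]/[filter_tracks()].
#' @param truth a `ground_truth`.
#' @param match_radius_px per-frame matching radius (default 2).
#' @param coverage_min fraction of an object's frames that correctly
#'   identified track frames must cover (default 0.9).
#' @return List with `recovery` (fraction of objects recovered), `n_switches`
#'   (total identity switches across tracks), `per_object` coverage table.
#' @export
tracking_performance <- function(tracks, truth, match_radius_px = 2,
                                 coverage_min = 0.9) {
  tt <- truth$true_tracks
  true_by <- split(tt, tt$frame)
  assign_obj <- function(frame, x, y) {
    tr <- true_by[[as.character(frame)]]
    if (is.null(tr)) return(NA_integer_)
    d2 <- (tr$x_px - x)^2 + (tr$y_px - y)^2
    i <- which.min(d2)
    if (d2[i] <= match_radius_px^2) tr$object_id[i] else NA_integer_
  }
  objs <- sort(unique(tt$object_id))
  covered <- stats::setNames(rep(0L, length(objs)), objs)
  n_switch <- 0L
  for (id in unique(tracks$track_id)) {
    trk <- tracks[tracks$track_id == id, , drop = FALSE]
    a <- mapply(assign_obj, trk$frame, trk$x_px, trk$y_px)
    a_def <- a[!is.na(a)]
    if (length(a_def) == 0L) next
    runs <- rle(a_def)
    n_switch <- n_switch + (length(runs$values) - 1L)
    majority <- as.character(names(which.max(table(a_def))))
    covered[majority] <- covered[majority] + sum(a_def == as.integer(majority))
  }
  frames_per_obj <- table(tt$object_id)
  cov_frac <- covered / as.numeric(frames_per_obj[names(covered)])
  list(recovery = mean(cov_frac >= coverage_min),
       n_switches = n_switch,
       per_object = data.frame(object_id = as.integer(names(cov_frac)),
                               coverage = as.numeric(cov_frac)))
}
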