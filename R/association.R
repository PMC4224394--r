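# Sticky per-frame reference assignment: at each frame the object is
# associated with a reference object if one lies within radius_px of its
# position; while the current reference stays within the radius it is kept,
# otherwise the nearest in-radius reference takes over. Returns the ref_id
# per frame (NA when not associated).
sticky_ref_sequence <- function(frames, x, y, ref_positions, radius_px) {
  out <- rep(NA_integer_, length(frames))
  if (nrow(ref_positions) == 0L) return(out)
  ref_by_frame <- split(ref_positions, ref_positions$frame)
  current <- NA_integer_
  for (k in seq_along(frames)) {
    refs <- ref_by_frame[[as.character(frames[k])]]
    if (is.null(refs) || nrow(refs) == 0L) {
      current <- NA_integer_
      next
    }
    d2 <- (refs$x_px - x[k])^2 + (refs$y_px - y[k])^2
    within <- d2 <= radius_px^2
    if (!is.na(current) && any(within & refs$ref_id == current)) {
      out[k] <- current
    } else if (any(within)) {
      cand <- which(within)
      out[k] <- refs$ref_id[cand[which.min(d2[cand])]]
      current <- out[k]
    } else {
      current <- NA_integer_
    }
  }
  out
}

#' Object-based colocalization fraction
#'
#' Fraction of objects in set A whose nearest object centroid in set B lies
#' within `radius_px`. The measure is directional: `coloc(A, B)` and
#' `coloc(B, A)` generally differ, and both directions should be reported.
#'
#' @param dets_a,dets_b data.frames with `x_px`, `y_px` from the same frame or
#'   field.
#' @param radius_px matching radius in pixels (>= 0).
#' @return Fraction in [0, 1]; `NA` when A is empty (undefined, not 0).
#' @export
object_coloc_fraction <- function(dets_a, dets_b, radius_px) {
  if (radius_px < 0) stop("radius_px must be >= 0", call. = FALSE)
  if (nrow(dets_a) == 0L) return(NA_real_)
  if (nrow(dets_b) == 0L) return(0)
  d2 <- outer(dets_a$x_px, dets_b$x_px, "-")^2 +
        outer(dets_a$y_px, dets_b$y_px, "-")^2
  mean(apply(d2, 1L, min) <= radius_px^2)
}

#' Colocalization time course between two detection channels
#'
#' Per time bin, the object-based colocalization fraction of channel A
#' against channel B, where objects are matched within the same frame and
#' pooled over the frames of the bin.
#'
#' @param dets_a,dets_b per-frame detection tables (`frame`, `x_px`, `y_px`).
#' @param radius_px matching radius in pixels.
#' @param metadata a [movie_metadata()] (supplies the frame interval).
#' @param bin_frames number of frames per time bin (default 1).
#' @return data.frame with `frame_mid`, `time_s`, `fraction`, `n_objects`
#'   (number of A objects in the bin; `fraction` is `NA` when 0).
#' @export
coloc_time_course <- function(dets_a, dets_b, radius_px, metadata,
                              bin_frames = 1L) {
  stopifnot(inherits(metadata, "movie_metadata"), bin_frames >= 1L)
  n <- metadata$n_frames
  dt_s <- metadata$frame_interval_ms / 1000
  starts <- seq(0L, n - 1L, by = bin_frames)
  out <- data.frame(frame_mid = numeric(0), time_s = numeric(0),
                    fraction = numeric(0), n_objects = integer(0))
  a_by <- split(dets_a, dets_a$frame)
  b_by <- split(dets_b, dets_b$frame)
  for (s in starts) {
    fr <- s:min(s + bin_frames - 1L, n - 1L)
    hits <- 0L; total <- 0L
    for (f in fr) {
      a <- a_by[[as.character(f)]]
      if (is.null(a) || nrow(a) == 0L) next
      b <- b_by[[as.character(f)]]
      if (is.null(b)) b <- data.frame(x_px = numeric(), y_px = numeric())
      frac <- object_coloc_fraction(a, b, radius_px)
      hits <- hits + round(frac * nrow(a))
      total <- total + nrow(a)
    }
    out <- rbind(out, data.frame(
      frame_mid = mean(fr),
      time_s = mean(fr) * dt_s,
      fraction = if (total > 0L) hits / total else NA_real_,
      n_objects = total))
  }
  out
}

#' Association runs of a track on reference-channel structures
#'
#' Frame bookkeeping of coat-organelle association: per frame the track is
#' associated when it lies within `radius_px` of a reference object, with a
#' sticky assignment that keeps the current reference while it stays in
#' radius. Maximal runs of the same reference, allowing internal
#' non-associated gaps of at most `max_gap_frames` frames, become events.
#' Events touching the first or last frame of the track are flagged
#' `censored`: their true duration is only bounded below.
#'
#' @param track one track's data.frame (`frame`, `x_px`, `y_px`, optionally
#'   `track_id`).
#' @param ref_positions reference detections (`ref_id`, `frame`, `x_px`,
#'   `y_px`) covering the track's frame span.
#' @param radius_px association radius in pixels (default 3, the spatial
#'   scale of the motility criterion).
#' @param max_gap_frames internal gap tolerance in frames (default 0, strict).
#' @param metadata a [movie_metadata()]; supplies the frame interval for
#'   `dwell_s`.
#' @return data.frame of class `association_events`: `track_id`, `ref_id`,
#'   `start_frame`, `end_frame` (inclusive), `n_gap_frames`, `dwell_s`,
#'   `censored`.
#' @export
association_runs <- function(track, ref_positions, radius_px = 3,
                             max_gap_frames = 0L, metadata = NULL) {
  tr <- track[order(track$frame), , drop = FALSE]
  dt_s <- if (is.null(metadata)) NA_real_ else metadata$frame_interval_ms / 1000
  tid <- if ("track_id" %in% names(tr)) tr$track_id[1] else NA_integer_
  empty <- data.frame(track_id = integer(), ref_id = integer(),
                      start_frame = integer(), end_frame = integer(),
                      n_gap_frames = integer(), dwell_s = numeric(),
                      censored = logical())
  if (nrow(tr) == 0L) return(empty)
  seq_ref <- sticky_ref_sequence(tr$frame, tr$x_px, tr$y_px,
                                 ref_positions, radius_px)
  events <- list()
  i <- 1L
  n <- length(seq_ref)
  while (i <= n) {
    if (is.na(seq_ref[i])) { i <- i + 1L; next }
    rid <- seq_ref[i]
    start <- i; end <- i; gaps <- 0L
    j <- i + 1L
    while (j <= n) {
      if (!is.na(seq_ref[j]) && seq_ref[j] == rid) {
        gaps <- gaps + (j - end - 1L)
        end <- j
        j <- j + 1L
      } else if (is.na(seq_ref[j]) && (j - end) <= max_gap_frames) {
        j <- j + 1L
      } else break
    }
    n_frames <- end - start + 1L
    events[[length(events) + 1L]] <- data.frame(
      track_id = tid, ref_id = rid,
      start_frame = tr$frame[start], end_frame = tr$frame[end],
      n_gap_frames = gaps,
      dwell_s = n_frames * dt_s,
      censored = (start == 1L) || (end == n))
    i <- end + 1L
  }
  if (length(events) == 0L) return(empty)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  class(out) <- c("association_events", class(out))
  out
}

#' Association runs for every track in a table
#'
#' @param tracks data.frame as returned by [build_tracks()] (ideally after
#'   [filter_tracks()]).
#' @inheritParams association_runs
#' @return Row-bound [association_runs()] events for all tracks.
#' @export
association_runs_all <- function(tracks, ref_positions, radius_px = 3,
                                 max_gap_frames = 0L, metadata = NULL) {
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id)
    association_runs(tracks[tracks$track_id == id, , drop = FALSE],
                     ref_positions, radius_px, max_gap_frames, metadata))
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- association_runs(tracks[0, , drop = FALSE], ref_positions,
                            radius_px, max_gap_frames, metadata)
  rownames(res) <- NULL
  res
}

#' Dwell-time summary of association events
#'
#' Summarizes `dwell_s` over events. By default censored events (runs
#' truncated by a track boundary) are excluded, since their durations are
#' right-truncated and would bias the mean downward.
#'
#' @param events an [association_runs()] table.
#' @param censoring `"exclude"` (default) or `"include"`.
#' @param breaks histogram breaks specification passed to [graphics::hist()].
#' @return List with `mean_s`, `median_s`, `n`, `histogram` (counts per bin).
#' @export
dwell_stats <- function(events, censoring = c("exclude", "include"),
                        breaks = "Sturges") {
  censoring <- match.arg(censoring)
  if (nrow(events) == 0L) stop("no association events", call. = FALSE)
  ev <- if (censoring == "exclude") events[!events$censored, , drop = FALSE]
        else events
  if (nrow(ev) == 0L)
    stop("all events are censored; no estimable dwell times", call. = FALSE)
  h <- graphics::hist(ev$dwell_s, breaks = breaks, plot = FALSE)
  list(mean_s = mean(ev$dwell_s),
       median_s = stats::median(ev$dwell_s),
       n = nrow(ev),
       histogram = data.frame(mid_s = h$mids, count = h$counts))
}
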