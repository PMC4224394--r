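#' Linking parameters for frame-to-frame assignment
#'
#' The cost of linking detection i (frame t) to detection j (frame t+1) is
#' `w_dist * d_ij / gate_radius_px + w_int * |I_i - I_j| / intensity_scale`,
#' with links beyond `gate_radius_px` forbidden. Leaving a detection unlinked
#' (track death or birth) costs `cost_unmatched`, so a pair is linked only
#' when its cost beats two unlinked detections (`2 * cost_unmatched`).
#'
#' @param gate_radius_px maximum linking displacement in pixels (> 0).
#' @param w_dist,w_int non-negative cost weights (their sum must be > 0).
#' @param intensity_scale normalizer for intensity differences; `NULL` means
#'   the median detection intensity of the data being linked.
#' @param cost_unmatched birth/death cost; default `w_dist + w_int`.
#' @return A list of class `link_params`.
#' @export
link_params <- function(gate_radius_px = 5, w_dist = 1, w_int = 0.5,
                        intensity_scale = NULL,
                        cost_unmatched = w_dist + w_int) {
  if (gate_radius_px <= 0) stop("gate_radius_px must be positive", call. = FALSE)
  if (w_dist < 0 || w_int < 0 || w_dist + w_int <= 0)
    stop("weights must be non-negative with a positive sum", call. = FALSE)
  structure(list(gate_radius_px = gate_radius_px, w_dist = w_dist,
                 w_int = w_int, intensity_scale = intensity_scale,
                 cost_unmatched = cost_unmatched),
            class = "link_params")
}

# Jonker-Volgenant style shortest-augmenting-path solver for the square
# linear assignment problem. Returns the column assigned to each row.
# Deterministic for a given cost matrix.
solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # column potentials, v[1] is the virtual column 0
  p <- integer(n + 1L)     # p[j+1]: row assigned to column j (0 = free)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    way <- integer(n)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      k <- which.min(minv[free])
      j1 <- free[k]
      delta <- minv[j1]
      usedj <- which(used) - 1L   # columns (0-based) in the alternating tree
      for (j in usedj) {
        u[p[j + 1L]] <- u[p[j + 1L]] + delta
        v[j + 1L] <- v[j + 1L] - delta
      }
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  assignment
}

# Pairwise link costs with gating; Inf marks a forbidden pair.
link_cost_matrix <- function(dets_t, dets_t1, params, intensity_scale) {
  nt <- nrow(dets_t); nt1 <- nrow(dets_t1)
  dx <- outer(dets_t$x_px, dets_t1$x_px, "-")
  dy <- outer(dets_t$y_px, dets_t1$y_px, "-")
  d <- sqrt(dx^2 + dy^2)
  di <- abs(outer(dets_t$intensity, dets_t1$intensity, "-"))
  cost <- params$w_dist * d / params$gate_radius_px +
    params$w_int * di / intensity_scale
  cost[d > params$gate_radius_px] <- Inf
  cost
}

#' Globally optimal linking of two consecutive detection sets
#'
#' Minimizes the total distance+intensity cost over one-to-one partial
#' assignments, with unmatched detections (births/deaths) charged
#' `cost_unmatched` each and pairs beyond the gating radius forbidden. Solved
#' exactly on the standard augmented (birth/death dummy) cost matrix.
#'
#' @param dets_t,dets_t1 data.frames with `x_px`, `y_px`, `intensity` for two
#'   consecutive frames.
#' @param params a [link_params()].
#' @return data.frame with columns `i`, `j`: row indices into `dets_t` and
#'   `dets_t1` of the linked pairs (zero rows when nothing links).
#' @export
link_frames <- function(dets_t, dets_t1, params = link_params()) {
  nt <- nrow(dets_t); nt1 <- nrow(dets_t1)
  empty <- data.frame(i = integer(), j = integer())
  if (nt == 0L || nt1 == 0L) return(empty)
  iscale <- params$intensity_scale
  if (is.null(iscale))
    iscale <- stats::median(c(dets_t$intensity, dets_t1$intensity))
  if (!is.finite(iscale) || iscale <= 0) iscale <- 1
  cost <- link_cost_matrix(dets_t, dets_t1, params, iscale)
  b <- params$cost_unmatched
  big <- 1e8
  n <- nt + nt1
  aug <- matrix(big, n, n)
  finite <- is.finite(cost)
  aug[seq_len(nt), seq_len(nt1)][finite] <- cost[finite]
  for (i in seq_len(nt)) aug[i, nt1 + i] <- b            # death of i
  for (j in seq_len(nt1)) aug[nt + j, j] <- b            # birth of j
  aug[(nt + 1L):n, (nt1 + 1L):n] <- 0                    # dummy-dummy, free
  assignment <- solve_lap(aug)
  links <- data.frame(i = seq_len(nt), j = assignment[seq_len(nt)])
  links <- links[links$j <= nt1, , drop = FALSE]
  # guard: never emit a forbidden link (cannot happen unless big is undercut)
  links <- links[is.finite(cost[cbind(links$i, links$j)]), , drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Assemble tracks by chaining successive frame links
#'
#' Detections are sorted by (frame, x, y) for determinism, then linked frame
#' by frame with [link_frames()]. A track ends whenever its detection finds no
#' match in the next frame; there is no gap closing, so track frames are
#' strictly consecutive. Detections that end up alone (length-1 chains) are
#' discarded as singletons; their count is attached as attribute
#' `n_singletons`.
#'
#' @param detections data.frame with `frame` (0-based integers), `x_px`,
#'   `y_px`, `intensity`.
#' @param params a [link_params()].
#' @return data.frame with columns `track_id`, `frame`, `x_px`, `y_px`,
#'   `intensity`, ordered by track then frame.
#' @export
build_tracks <- function(detections, params = link_params()) {
  cols <- c("frame", "x_px", "y_px", "intensity")
  stopifnot(all(cols %in% names(detections)))
  empty <- data.frame(track_id = integer(), frame = integer(),
                      x_px = numeric(), y_px = numeric(),
                      intensity = numeric())
  if (nrow(detections) == 0L) {
    attr(empty, "n_singletons") <- 0L
    return(empty)
  }
  if (any(detections$frame != floor(detections$frame)))
    stop("frame indices must be integers", call. = FALSE)
  det <- detections[order(detections$frame, detections$x_px, detections$y_px), ,
                    drop = FALSE]
  rownames(det) <- NULL
  if (is.null(params$intensity_scale)) {
    params$intensity_scale <- stats::median(det$intensity)
    if (!is.finite(params$intensity_scale) || params$intensity_scale <= 0)
      params$intensity_scale <- 1
  }
  frames <- sort(unique(det$frame))
  by_frame <- split(seq_len(nrow(det)), det$frame)

  track_of <- integer(nrow(det))   # 0 = not yet assigned
  next_id <- 0L
  open <- integer(0)               # det row index of each open track's head
  for (fi in seq_along(frames)) {
    rows <- by_frame[[as.character(frames[fi])]]
    if (fi == 1L || (frames[fi] - frames[fi - 1L]) != 1L) {
      open_rows <- integer(0)
    } else {
      open_rows <- open
    }
    if (length(open_rows) > 0L) {
      links <- link_frames(det[open_rows, , drop = FALSE],
                           det[rows, , drop = FALSE], params)
    } else {
      links <- data.frame(i = integer(), j = integer())
    }
    new_open <- integer(length(rows))
    matched_j <- integer(0)
    if (nrow(links) > 0L) {
      for (r in seq_len(nrow(links))) {
        prev_row <- open_rows[links$i[r]]
        cur_row <- rows[links$j[r]]
        if (track_of[prev_row] == 0L) {
          next_id <- next_id + 1L
          track_of[prev_row] <- next_id
        }
        track_of[cur_row] <- track_of[prev_row]
      }
      matched_j <- links$j
    }
    open <- rows
    invisible(new_open)
  }
  keep <- track_of > 0L
  n_singletons <- sum(!keep)
  out <- det[keep, cols, drop = FALSE]
  out$track_id <- track_of[keep]
  # renumber tracks by first appearance
  first_seen <- !duplicated(out$track_id)
  relabel <- integer(max(out$track_id))
  relabel[out$track_id[first_seen]] <- seq_len(sum(first_seen))
  out$track_id <- relabel[out$track_id]
  out <- out[order(out$track_id, out$frame), c("track_id", cols), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_singletons") <- n_singletons
  out
}

#' Track-length filter
#'
#' Retains tracks spanning at least `min_frames` detections. The default of 6
#' implements the strict reading of the published rule that only trajectories
#' of more than 5 consecutive frames are considered.
#'
#' @param tracks data.frame as returned by [build_tracks()].
#' @param min_frames minimum number of detections per track (>= 2).
#' @return Filtered tracks data.frame.
#' @export
filter_tracks <- function(tracks, min_frames = 6L) {
  if (min_frames < 2L) stop("min_frames must be >= 2", call. = FALSE)
  if (nrow(tracks) == 0L) return(tracks)
  len <- table(tracks$track_id)
  keep_ids <- as.integer(names(len)[len >= min_frames])
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}
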