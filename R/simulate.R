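#' Generate a filament field for the binding geometry
#'
#' Lays down `n_filaments` persistent random-walk polylines (the analogue of
#' septin-decorated actin filaments) to which simulated objects anchor during
#' bound states. Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list of class `filament_field` with element `filaments`, a list of
#'   two-column (x, y) matrices in 0-based pixel coordinates, all vertices
#'   inside the field.
#' @export
make_filament_field <- function(config) {
  validate_sim_config(config)
  ny <- config$field_size_px[1]
  nx <- config$field_size_px[2]
  set.seed(config$seed + 11L)

  step <- 3
  n_steps <- ceiling(1.5 * max(nx, ny) / step)
  filaments <- vector("list", config$n_filaments)
  for (f in seq_len(config$n_filaments)) {
    x <- numeric(n_steps + 1L)
    y <- numeric(n_steps + 1L)
    x[1] <- stats::runif(1, 0, nx - 1)
    y[1] <- stats::runif(1, 0, ny - 1)
    theta <- stats::runif(1, 0, 2 * pi)
    for (s in seq_len(n_steps)) {
      theta <- theta + stats::rnorm(1, 0, config$filament_persistence)
      px <- x[s] + step * cos(theta)
      py <- y[s] + step * sin(theta)
      # reflect the walk so vertices stay inside the field
      rx <- reflect_coord(px, 0, nx - 1)
      ry <- reflect_coord(py, 0, ny - 1)
      if (rx$flipped) theta <- pi - theta
      if (ry$flipped) theta <- -theta
      x[s + 1L] <- rx$value
      y[s + 1L] <- ry$value
    }
    filaments[[f]] <- cbind(x = x, y = y)
  }
  structure(list(filaments = filaments,
                 field_size_px = config$field_size_px),
            class = "filament_field")
}

# Reflect a scalar coordinate into [lo, hi]; reports whether the direction of
# travel was inverted an odd number of times.
reflect_coord <- function(p, lo, hi) {
  r <- hi - lo
  q <- (p - lo) %% (2 * r)
  flipped <- q > r
  q <- ifelse(flipped, 2 * r - q, q)
  n_folds <- floor((p - lo) / r)
  list(value = lo + q, flipped = (n_folds %% 2) != 0)
}

# Resample filament polylines to a dense point set for nearest-point queries.
filament_points <- function(field, spacing = 0.5) {
  pts <- lapply(field$filaments, function(poly) {
    if (nrow(poly) < 2L) return(poly)
    out <- list()
    for (s in seq_len(nrow(poly) - 1L)) {
      a <- poly[s, ]; b <- poly[s + 1L, ]
      len <- sqrt(sum((b - a)^2))
      n <- max(1L, ceiling(len / spacing))
      tt <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
      out[[s]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
    }
    do.call(rbind, out)
  })
  do.call(rbind, pts)
}

#' Simulate two-state trajectories with full ground truth
#'
#' Each object alternates between a bound state (stationary at an anchor,
#' jittered by `localization_jitter_px`) and a motile state (directed motion
#' at `motile_speed_um_s`). Bound sojourns are exponential with mean
#' `bound_dwell_s`. A motile excursion lasts an exponential time with mean
#' `free_dwell_s` and ends in one of two ways: with probability calibrated to
#' `ref_channel$coloc_fraction` the object is transported directly (constant
#' speed, straight heading) to its target reference compartment and docks
#' there; otherwise it keeps wandering (slowly diffusing heading) until it
#' encounters a filament, where it rebinds. Docked objects ride their
#' (slowly drifting) reference compartment; each object has a dedicated
#' target compartment, so two objects never dock on the same one. Rebinding
#' avoids sites currently occupied by other objects and the vicinity of
#' reference compartments. Switching happens in continuous time; positions
#' are sampled on the frame grid; boundaries are reflective, so the object
#' count is constant.
#'
#' Reference compartments (one per object, capped at `ref_channel$count`) are
#' placed on filaments with mutual separation of at least four association
#' radii. The docking probability per excursion is set so that the expected
#' fraction of vesicle object-frames lying within `ref_channel$radius_px` of
#' a reference compartment matches `ref_channel$coloc_fraction`. An optional
#' `ref_channel$ramp = list(peak_frame, sd_frames)` modulates the docking
#' probability over time with a Gaussian profile (an association wave rising
#' and falling over the series).
#'
#' @param config a [sim_config()].
#' @param field a [make_filament_field()] result; defaults to generating one
#'   from `config`.
#' @return A list of class `ground_truth` with elements
#'   `true_tracks` (data.frame: object_id, frame, x_px, y_px, state),
#'   `bound_intervals` (data.frame of bound sojourns with their anchors and,
#'   for docked sojourns, the reference id), `association_intervals`
#'   (data.frame: object_id, ref_id, start_frame, end_frame), and
#'   `ref_positions` (data.frame: ref_id, frame, x_px, y_px).
#' @export
simulate_tracks <- function(config, field = make_filament_field(config)) {
  validate_sim_config(config)
  ny <- config$field_size_px[1]
  nx <- config$field_size_px[2]
  set.seed(config$seed + 23L)

  dt <- config$frame_interval_ms / 1000          # s/frame
  v_px_s <- speed_px_per_frame(config) / dt      # px/s
  jit <- config$localization_jitter_px
  n <- config$n_frames
  rc <- config$ref_channel
  margin <- 2
  lo <- margin; hix <- nx - 1 - margin; hiy <- ny - 1 - margin
  fil_pts <- if (config$n_filaments > 0L) filament_points(field) else NULL
  capture <- config$capture_radius_px

  ## --- reference compartments: one dedicated target per object ------------
  n_ref <- if (rc$coloc_fraction > 0) min(rc$count, config$n_objects) else 0L
  ref_base <- matrix(numeric(0), ncol = 2)
  if (n_ref > 0L) {
    min_sep <- 4 * rc$radius_px
    cand_pool <- if (!is.null(fil_pts)) fil_pts else
      cbind(stats::runif(1000, lo, hix), stats::runif(1000, lo, hiy))
    ok <- cand_pool[, 1] >= lo + min_sep / 2 & cand_pool[, 1] <= hix - min_sep / 2 &
          cand_pool[, 2] >= lo + min_sep / 2 & cand_pool[, 2] <= hiy - min_sep / 2
    pool <- cand_pool[ok, , drop = FALSE]
    if (nrow(pool) == 0L) pool <- cand_pool
    for (tries in seq_len(2000L)) {
      if (nrow(ref_base) >= n_ref) break
      p <- pool[sample.int(nrow(pool), 1L), ]
      if (nrow(ref_base) == 0L ||
          all((ref_base[, 1] - p[1])^2 + (ref_base[, 2] - p[2])^2 >= min_sep^2))
        ref_base <- rbind(ref_base, p)
    }
    n_ref <- nrow(ref_base)
  }
  ref_paths <- lapply(seq_len(n_ref), function(r) {
    cbind(ref_base[r, 1] + cumsum(stats::rnorm(n, 0, rc$drift_sd_px)),
          ref_base[r, 2] + cumsum(stats::rnorm(n, 0, rc$drift_sd_px)))
  })

  ## --- docking probability calibrated to the target coloc fraction --------
  e_travel <- if (n_ref > 0L) {
    gx <- stats::runif(200, lo, hix); gy <- stats::runif(200, lo, hiy)
    mean(vapply(seq_along(gx), function(i)
      min(sqrt((ref_base[, 1] - gx[i])^2 + (ref_base[, 2] - gy[i])^2)),
      numeric(1))) / v_px_s
  } else 0
  e_seek <- 1.0   # rough mean filament-encounter time after clock expiry, s
  p_dock <- 0
  if (n_ref > 0L && rc$coloc_fraction > 0) {
    p_dock <- rc$coloc_fraction
    for (it in 1:5) {
      cycle <- config$bound_dwell_s + config$free_dwell_s +
        p_dock * e_travel + (1 - p_dock) * e_seek
      bound_frac <- config$bound_dwell_s / cycle
      p_dock <- min(1, rc$coloc_fraction / bound_frac)
    }
  }
  ramp_factor <- function(t_frame) {
    if (is.null(rc$ramp)) return(1)
    exp(-(t_frame - rc$ramp$peak_frame)^2 / (2 * rc$ramp$sd_frames^2))
  }

  ## --- per-object shared bookkeeping ---------------------------------------
  # registry of filament-anchor occupations (x, y, start_frame, end_frame)
  registry <- matrix(numeric(0), ncol = 4)
  anchor_counter <- 0L
  all_tracks <- vector("list", config$n_objects)

  # nearest free filament point within the capture radius (NULL when none):
  # avoids reference vicinities and currently occupied anchors
  filament_contact <- function(x, y, k) {
    if (is.null(fil_pts)) return(NULL)
    d2 <- (fil_pts[, 1] - x)^2 + (fil_pts[, 2] - y)^2
    ord <- which(d2 <= capture^2)
    if (length(ord) == 0L) return(NULL)
    ord <- ord[order(d2[ord])]
    for (i in ord) {
      p <- fil_pts[i, ]
      if (n_ref > 0L &&
          any((ref_base[, 1] - p[1])^2 + (ref_base[, 2] - p[2])^2 <=
              (2 * rc$radius_px)^2)) next
      if (nrow(registry) > 0L) {
        act <- registry[, 3] <= k & registry[, 4] >= k
        if (any(act & (registry[, 1] - p[1])^2 + (registry[, 2] - p[2])^2 <= 16))
          next
      }
      return(c(min(max(p[1], lo), hix), min(max(p[2], lo), hiy)))
    }
    NULL
  }

  nearest_anchor <- function(x, y, k) {
    if (is.null(fil_pts)) return(c(x, y))
    ok <- rep(TRUE, nrow(fil_pts))
    if (n_ref > 0L)
      for (r in seq_len(n_ref))
        ok <- ok & ((fil_pts[, 1] - ref_base[r, 1])^2 +
                    (fil_pts[, 2] - ref_base[r, 2])^2 > (2 * rc$radius_px)^2)
    if (nrow(registry) > 0L) {
      act <- which(registry[, 3] <= k & registry[, 4] >= k)
      for (i in act)
        ok <- ok & ((fil_pts[, 1] - registry[i, 1])^2 +
                    (fil_pts[, 2] - registry[i, 2])^2 > 16)
    }
    cand <- if (any(ok)) fil_pts[ok, , drop = FALSE] else fil_pts
    d2 <- (cand[, 1] - x)^2 + (cand[, 2] - y)^2
    p <- cand[which.min(d2), ]
    c(min(max(p[1], lo), hix), min(max(p[2], lo), hiy))
  }

  cycle0 <- config$bound_dwell_s + config$free_dwell_s +
    p_dock * e_travel + (1 - p_dock) * e_seek
  p_bound0 <- config$bound_dwell_s / cycle0

  for (obj in seq_len(config$n_objects)) {
    my_ref <- if (n_ref > 0L) ((obj - 1L) %% n_ref) + 1L else 0L
    x <- stats::runif(1, lo, hix)
    y <- stats::runif(1, lo, hiy)
    heading <- stats::runif(1, 0, 2 * pi)
    # phases: bound_fil (anchored to filament), docked (on reference),
    #         wander (free excursion), travel (transport to reference),
    #         seek (free excursion past its clock, rebinding on contact)
    # stationary initial state: bound (docked or on a filament) or wandering;
    # the residual sojourn of an exponential state is again exponential
    u0 <- stats::runif(1)
    phase <- if (u0 < p_bound0 * p_dock * ramp_factor(1)) "docked"
             else if (u0 < p_bound0) "bound_fil" else "wander"
    if (phase == "docked" && my_ref == 0L) phase <- "bound_fil"
    anchor <- c(NA_real_, NA_real_)
    anchor_id <- NA_integer_
    anchor_start <- NA_integer_
    if (phase == "bound_fil") {
      anchor <- nearest_anchor(x, y, 1L)
      x <- anchor[1]; y <- anchor[2]
      anchor_counter <- anchor_counter + 1L
      anchor_id <- anchor_counter
      anchor_start <- 1L
    } else if (phase == "docked") {
      x <- ref_paths[[my_ref]][1, 1]; y <- ref_paths[[my_ref]][1, 2]
      anchor_counter <- anchor_counter + 1L
      anchor_id <- anchor_counter
    }
    t_end <- stats::rexp(1, 1 / if (phase %in% c("bound_fil", "docked"))
                                  config$bound_dwell_s
                                else config$free_dwell_s)

    fx <- numeric(n); fy <- numeric(n)
    fstate <- character(n); faid <- integer(n); fref <- integer(n)

    advance <- function(d, k) {
      # move for duration d within frame k (motile phases only)
      if (d <= 0 || phase %in% c("bound_fil", "docked")) return(invisible())
      if (phase == "travel") {
        tgt <- ref_paths[[my_ref]][k, ]
        heading <<- atan2(tgt[2] - y, tgt[1] - x)
      } else {
        heading <<- heading +
          stats::rnorm(1, 0, config$heading_sd_rad * sqrt(d / dt))
      }
      step <- v_px_s * d
      if (phase == "travel") {
        tgt <- ref_paths[[my_ref]][k, ]
        togo <- sqrt((tgt[1] - x)^2 + (tgt[2] - y)^2)
        step <- min(step, togo)   # do not overshoot the target
      }
      px <- x + step * cos(heading)
      py <- y + step * sin(heading)
      rx <- reflect_coord(px, lo, hix)
      ry <- reflect_coord(py, lo, hiy)
      if (rx$flipped) heading <<- pi - heading
      if (ry$flipped) heading <<- -heading
      x <<- rx$value; y <<- ry$value
      invisible()
    }

    close_anchor <- function(k_end) {
      # record a finished filament occupation for later objects to avoid
      if (!is.na(anchor_start))
        registry <<- rbind(registry, c(anchor[1], anchor[2], anchor_start, k_end))
      anchor_start <<- NA_integer_
    }

    for (k in seq_len(n)) {
      t_k <- (k - 1) * dt
      if (phase == "bound_fil") {
        fx[k] <- anchor[1] + stats::rnorm(1, 0, jit)
        fy[k] <- anchor[2] + stats::rnorm(1, 0, jit)
        faid[k] <- anchor_id; fref[k] <- NA_integer_
        fstate[k] <- "bound"
      } else if (phase == "docked") {
        rp <- ref_paths[[my_ref]][k, ]
        fx[k] <- rp[1] + stats::rnorm(1, 0, jit)
        fy[k] <- rp[2] + stats::rnorm(1, 0, jit)
        faid[k] <- anchor_id; fref[k] <- my_ref
        fstate[k] <- "bound"
      } else {
        fx[k] <- x; fy[k] <- y
        faid[k] <- NA_integer_; fref[k] <- NA_integer_
        fstate[k] <- "motile"
      }
      # advance the clock from t_k to t_k + dt, handling in-frame switches
      tau <- t_k
      while (t_end < t_k + dt) {
        advance(t_end - tau, k)
        tau <- t_end
        if (phase %in% c("bound_fil", "docked")) {
          if (phase == "bound_fil") {
            close_anchor(k)
            x <- anchor[1]; y <- anchor[2]
          } else {
            x <- ref_paths[[my_ref]][k, 1]
            y <- ref_paths[[my_ref]][k, 2]
          }
          phase <- "wander"
          heading <- stats::runif(1, 0, 2 * pi)
          anchor <- c(NA_real_, NA_real_); anchor_id <- NA_integer_
          t_end <- tau + stats::rexp(1, 1 / config$free_dwell_s)
        } else if (phase == "wander") {
          # excursion clock expired: dock or rebind
          if (my_ref > 0L && stats::runif(1) < p_dock * ramp_factor(k)) {
            phase <- "travel"
          } else if (is.null(fil_pts)) {
            phase <- "bound_fil"      # no filaments: rebind in place
            anchor <- c(x, y)
            anchor_counter <- anchor_counter + 1L
            anchor_id <- anchor_counter
            anchor_start <- k
            t_end <- tau + stats::rexp(1, 1 / config$bound_dwell_s)
            next
          } else {
            phase <- "seek"
          }
          t_end <- Inf
        } else break
      }
      advance(t_k + dt - tau, k)
      if (phase == "seek") {
        contact <- filament_contact(x, y, k)
        if (!is.null(contact)) {
          phase <- "bound_fil"
          anchor <- contact
          x <- anchor[1]; y <- anchor[2]
          anchor_counter <- anchor_counter + 1L
          anchor_id <- anchor_counter
          anchor_start <- k
          t_end <- (t_k + dt) + stats::rexp(1, 1 / config$bound_dwell_s)
        }
      } else if (phase == "travel") {
        rp <- ref_paths[[my_ref]][k, ]
        if ((rp[1] - x)^2 + (rp[2] - y)^2 <= capture^2) {
          phase <- "docked"
          anchor_counter <- anchor_counter + 1L
          anchor_id <- anchor_counter
          t_end <- (t_k + dt) + stats::rexp(1, 1 / config$bound_dwell_s)
        }
      }
    }
    if (phase == "bound_fil") close_anchor(n)

    all_tracks[[obj]] <- data.frame(object_id = obj, frame = 0:(n - 1L),
                                    x_px = fx, y_px = fy, state = fstate,
                                    anchor_id = faid, ref_id = fref)
  }

  true_tracks <- if (config$n_objects > 0L) do.call(rbind, all_tracks) else
    data.frame(object_id = integer(), frame = integer(), x_px = numeric(),
               y_px = numeric(), state = character(), anchor_id = integer(),
               ref_id = integer())
  rownames(true_tracks) <- NULL

  ref_positions <- if (n_ref > 0L) {
    rp <- do.call(rbind, lapply(seq_len(n_ref), function(r)
      data.frame(ref_id = r, frame = 0:(n - 1L),
                 x_px = ref_paths[[r]][, 1], y_px = ref_paths[[r]][, 2])))
    rownames(rp) <- NULL
    rp
  } else data.frame(ref_id = integer(), frame = integer(),
                    x_px = numeric(), y_px = numeric())

  bound_intervals <- extract_bound_intervals(true_tracks)
  assoc <- true_association_intervals(true_tracks, ref_positions,
                                      rc$radius_px)

  structure(list(
    true_tracks = true_tracks[, c("object_id", "frame", "x_px", "y_px", "state")],
    bound_intervals = bound_intervals,
    association_intervals = assoc,
    ref_positions = ref_positions,
    config = config
  ), class = "ground_truth")
}

# Maximal runs of constant anchor_id per object -> bound sojourn intervals,
# with the reference id for docked sojourns (NA for filament anchors).
extract_bound_intervals <- function(true_tracks) {
  out <- list()
  for (obj in unique(true_tracks$object_id)) {
    tt <- true_tracks[true_tracks$object_id == obj, ]
    aid <- tt$anchor_id
    if (all(is.na(aid))) next
    r <- rle(ifelse(is.na(aid), -1L, aid))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != -1L
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      object_id = obj,
      anchor_id = r$values[keep],
      start_frame = tt$frame[starts[keep]],
      end_frame = tt$frame[ends[keep]],
      ref_id = tt$ref_id[starts[keep]],
      anchor_x = vapply(which(keep), function(i)
        stats::median(tt$x_px[starts[i]:ends[i]]), numeric(1)),
      anchor_y = vapply(which(keep), function(i)
        stats::median(tt$y_px[starts[i]:ends[i]]), numeric(1))
    )
  }
  if (length(out) == 0L)
    return(data.frame(object_id = integer(), anchor_id = integer(),
                      start_frame = integer(), end_frame = integer(),
                      ref_id = integer(), anchor_x = numeric(),
                      anchor_y = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Ground-truth association intervals from true positions (sticky assignment,
# no gap tolerance) -- the oracle mirror of association_runs().
true_association_intervals <- function(true_tracks, ref_positions, radius_px) {
  empty <- data.frame(object_id = integer(), ref_id = integer(),
                      start_frame = integer(), end_frame = integer())
  if (nrow(ref_positions) == 0L || nrow(true_tracks) == 0L) return(empty)
  out <- list()
  for (obj in unique(true_tracks$object_id)) {
    tt <- true_tracks[true_tracks$object_id == obj, ]
    seq_ref <- sticky_ref_sequence(tt$frame, tt$x_px, tt$y_px,
                                   ref_positions, radius_px)
    r <- rle(ifelse(is.na(seq_ref), -1L, seq_ref))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values != -1L)
    for (i in keep)
      out[[length(out) + 1L]] <- data.frame(
        object_id = obj, ref_id = r$values[i],
        start_frame = tt$frame[starts[i]], end_frame = tt$frame[ends[i]])
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Render a two-channel movie from ground truth
#'
#' Image formation: every object becomes a 2-D Gaussian (vesicle channel:
#' width `psf_sigma_px`, peak `spot_amplitude`; reference channel: the larger,
#' dimmer `ref_channel` Gaussians) on a constant background. The whole frame
#' (signal and autofluorescent background) bleaches as
#' `exp(-frame/bleach_tau_frames)`. With `noise = TRUE` the expected image is
#' corrupted by Poisson shot noise plus Gaussian read noise and quantized to
#' 16-bit integer counts; with `noise = FALSE` the noiseless expected image is
#' returned (useful for calibration checks).
#'
#' @param truth a [simulate_tracks()] result.
#' @param config the [sim_config()] used to generate `truth`.
#' @param noise logical; add shot/read noise and quantize (default `TRUE`).
#' @return An `endo_movie`: list with `channels` (named list of ny x nx x T
#'   arrays, `vesicle` and `reference`) and `metadata` ([movie_metadata()]).
#' @export
render_movie <- function(truth, config, noise = TRUE) {
  validate_sim_config(config)
  stopifnot(inherits(truth, "ground_truth"))
  ny <- config$field_size_px[1]
  nx <- config$field_size_px[2]
  n <- config$n_frames
  set.seed(config$seed + 57L)

  render_channel <- function(pos_df, id_col, sigma, amplitude) {
    arr <- array(0, dim = c(ny, nx, n))
    spl <- if (nrow(pos_df) > 0L) split(pos_df, pos_df$frame) else list()
    for (k in seq_len(n)) {
      bleach <- exp(-(k - 1) / config$bleach_tau_frames)
      frame <- matrix(config$background, ny, nx)
      dets <- spl[[as.character(k - 1L)]]
      if (!is.null(dets) && nrow(dets) > 0L) {
        for (i in seq_len(nrow(dets)))
          frame <- add_gaussian_spot(frame, dets$x_px[i], dets$y_px[i],
                                     sigma, amplitude)
      }
      lam <- frame * bleach
      if (noise) {
        v <- stats::rpois(length(lam), lam) +
          stats::rnorm(length(lam), 0, config$read_noise_sd)
        lam <- matrix(pmin(65535, pmax(0, round(v))), ny, nx)
      }
      arr[, , k] <- lam
    }
    arr
  }

  channels <- list(
    vesicle = render_channel(truth$true_tracks, "object_id",
                             config$psf_sigma_px, config$spot_amplitude),
    reference = render_channel(truth$ref_positions, "ref_id",
                               config$ref_channel$psf_sigma_px,
                               config$ref_channel$amplitude)
  )
  structure(list(
    channels = channels,
    metadata = movie_metadata(config$pixel_size_nm, config$frame_interval_ms,
                              n, c("vesicle", "reference"))
  ), class = "endo_movie")
}

# Add one 2-D Gaussian (peak height `amplitude`, sd `sigma`) at 0-based
# pixel-center coordinates (x, y); truncated at 4 sigma.
add_gaussian_spot <- function(frame, x, y, sigma, amplitude) {
  ny <- nrow(frame); nx <- ncol(frame)
  r <- ceiling(4 * sigma)
  cols <- max(1L, floor(x + 1 - r)):min(nx, ceiling(x + 1 + r))
  rows <- max(1L, floor(y + 1 - r)):min(ny, ceiling(y + 1 + r))
  gx <- exp(-((cols - 1) - x)^2 / (2 * sigma^2))
  gy <- exp(-((rows - 1) - y)^2 / (2 * sigma^2))
  frame[rows, cols] <- frame[rows, cols] + amplitude * outer(gy, gx)
  frame
}

#' Simulate a complete synthetic acquisition
#'
#' Convenience wrapper: filament field, ground-truth trajectories and rendered
#' two-channel movie from one configuration. Bit-identical for a fixed
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param noise forwarded to [render_movie()].
#' @return List with `movie`, `truth`, `field`, `config`.
#' @export
simulate_movie <- function(config, noise = TRUE) {
  field <- make_filament_field(config)
  truth <- simulate_tracks(config, field)
  movie <- render_movie(truth, config, noise = noise)
  list(movie = movie, truth = truth, field = field, config = config)
}
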