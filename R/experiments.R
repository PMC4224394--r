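#' Motile-speed recovery experiment
#'
#' Generates control-condition synthetic acquisitions (600-frame series,
#' 143 nm pixels, 475 ms between frames, directed motile speed 1 um/s), runs
#' the full vesicle-channel pipeline (bleach correction, wavelet detection,
#' global linking, track-length filter, 3-px step classification) and pools
#' the motile-step displacements of all retained tracks into one mean speed.
#'
#' @param n_movies number of independent movies (default 10).
#' @param seed base seed; each movie uses a deterministic offset.
#' @param speed_um_s configured directed speed (default 1, the control value).
#' @param n_frames frames per movie (default 600).
#' @return List: `mean_motile_speed_um_s`, `n_motile_steps`, `n_tracks`,
#'   `per_movie` (data.frame of per-movie means).
#' @export
speed_recovery_experiment <- function(n_movies = 10L, seed = 1L,
                                      speed_um_s = 1.0, n_frames = 600L) {
  disp <- numeric(0)
  per_movie <- data.frame(movie = integer(), mean_speed_um_s = numeric(),
                          n_motile_steps = integer())
  n_tracks <- 0L
  for (i in seq_len(n_movies)) {
    cfg <- preset_control(n_frames = n_frames,
                          motile_speed_um_s = speed_um_s,
                          ref_channel = list(coloc_fraction = 0),
                          seed = seed + i * 101L)
    sim <- simulate_movie(cfg)
    arr <- bleach_correct(sim$movie$channels$vesicle, "first_frame")
    det <- detect_movie(arr, correct_bleach = FALSE)
    tracks <- filter_tracks(build_tracks(det), 6L)
    if (nrow(tracks) == 0L) next
    n_tracks <- n_tracks + length(unique(tracks$track_id))
    mot <- motility_summary(tracks, sim$movie$metadata, 3.0)
    d <- mot$steps$displacement_px[mot$steps$label == "motile"]
    sp <- px_frame_to_speed(cfg$pixel_size_nm, cfg$frame_interval_ms)
    per_movie <- rbind(per_movie, data.frame(
      movie = i, mean_speed_um_s = mean(d) * sp, n_motile_steps = length(d)))
    disp <- c(disp, d * sp)
  }
  list(mean_motile_speed_um_s = mean(disp),
       n_motile_steps = length(disp),
       n_tracks = n_tracks,
       per_movie = per_movie)
}

#' Dwell-time recovery experiment
#'
#' Generates extended control-condition two-channel acquisitions and
#' estimates the mean coat-compartment dwell time from uncensored
#' association runs (`max_gap_frames = 0`, censored events excluded). The
#' series are long (default 3000 frames at 475 ms, about 24 mean dwells) and
#' sparse (4 objects) because the mean of completed intervals inside a finite
#' observation window is biased low unless the window and the unbroken track
#' length both greatly exceed the mean dwell; the bleaching constant scales
#' with series length so the end-of-series signal-to-noise matches the
#' default preset.
#'
#' @param n_movies number of movies (default 3, about 140 uncensored events).
#' @param seed base seed.
#' @param bound_dwell_s configured mean bound dwell (default 60 s, the
#'   control association time).
#' @param n_frames frames per movie.
#' @param n_objects objects per movie.
#' @return List: `mean_dwell_s`, `mean_dwell_min`, `n_events`,
#'   `n_censored_excluded`.
#' @export
dwell_recovery_experiment <- function(n_movies = 3L, seed = 1L,
                                      bound_dwell_s = 60,
                                      n_frames = 3000L, n_objects = 4L) {
  dwells <- numeric(0)
  n_cens <- 0L
  for (i in seq_len(n_movies)) {
    cfg <- preset_control(n_frames = n_frames, n_objects = n_objects,
                          bound_dwell_s = bound_dwell_s,
                          bleach_tau_frames = n_frames,
                          seed = seed + i * 211L)
    res <- run_pipeline(cfg)
    ev <- res$events
    if (is.null(ev) || nrow(ev) == 0L) next
    u <- ev[!ev$censored, , drop = FALSE]
    n_cens <- n_cens + sum(ev$censored)
    dwells <- c(dwells, u$dwell_s)
  }
  list(mean_dwell_s = mean(dwells),
       mean_dwell_min = mean(dwells) / 60,
       n_events = length(dwells),
       n_censored_excluded = n_cens)
}
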