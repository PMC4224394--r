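#' Run the full analysis pipeline on one synthetic acquisition
#'
#' Chains the stages exactly as they would run on a real two-channel movie:
#' simulate, bleach-correct, detect spots in both channels, link and filter
#' vesicle tracks, classify step motility, compute track metrics, track the
#' reference channel (reference track ids serve as reference object ids), and
#' extract association runs and the colocalization time course.
#'
#' @param config a [sim_config()].
#' @param lparams a [link_params()].
#' @param min_frames track-length filter threshold (default 6).
#' @param threshold_px motility displacement threshold in pixels (default 3).
#' @param radius_px association/colocalization radius in pixels (default 3).
#' @param max_gap_frames association gap tolerance (default 0).
#' @param coloc_bin_frames time-bin width of the colocalization course.
#' @return List with `truth`, `detections` (vesicle), `ref_detections`
#'   (with `ref_id`), `tracks`, `metrics`, `steps`, `events`, `dwell`,
#'   `coloc`, `metadata`, `config`.
#' @export
run_pipeline <- function(config, lparams = link_params(), min_frames = 6L,
                         threshold_px = 3.0, radius_px = 3,
                         max_gap_frames = 0L, coloc_bin_frames = 25L) {
  sim <- simulate_movie(config)
  movie <- bleach_correct(sim$movie)
  md <- movie$metadata

  det_v <- detect_movie(movie, "vesicle", correct_bleach = FALSE)
  det_r <- detect_movie(movie, "reference", correct_bleach = FALSE)

  tracks <- filter_tracks(build_tracks(det_v, lparams), min_frames)
  mot <- if (nrow(tracks) > 0L) motility_summary(tracks, md, threshold_px)
         else list(metrics = NULL, steps = NULL)

  # reference objects are near-stationary; their tracks provide stable ids
  ref_tracks <- filter_tracks(build_tracks(det_r, lparams), min_frames)
  ref_dets <- if (nrow(ref_tracks) > 0L)
    data.frame(ref_id = ref_tracks$track_id, frame = ref_tracks$frame,
               x_px = ref_tracks$x_px, y_px = ref_tracks$y_px)
  else data.frame(ref_id = integer(), frame = integer(),
                  x_px = numeric(), y_px = numeric())

  events <- if (nrow(tracks) > 0L)
    association_runs_all(tracks, ref_dets, radius_px, max_gap_frames, md)
  else NULL
  dwell <- if (!is.null(events) && any(!events$censored))
    dwell_stats(events, "exclude") else NULL

  coloc <- coloc_time_course(det_v, det_r, radius_px, md, coloc_bin_frames)

  list(truth = sim$truth, detections = det_v, ref_detections = ref_dets,
       tracks = tracks, metrics = mot$metrics, steps = mot$steps,
       events = events, dwell = dwell, coloc = coloc,
       metadata = md, config = config)
}
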