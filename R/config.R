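#' Simulation configuration for synthetic two-channel movies
#'
#' Builds and validates the parameter set that drives the synthetic movie
#' generator: field geometry, acquisition calibration, the two-state
#' (filament-bound / motile) motion model, the image-formation model, and the
#' reference-channel layout.
#'
#' Durations of the bound and motile states are exponentially distributed with
#' means `bound_dwell_s` and `free_dwell_s`; motile motion is directed at
#' `motile_speed_um_s` with a slowly diffusing heading. Objects are rendered as
#' 2-D Gaussians of width `psf_sigma_px`, bleached as `exp(-t/bleach_tau_frames)`,
#' and corrupted by Poisson shot noise plus Gaussian read noise.
#'
#' @param field_size_px integer pair, frame size in pixels (rows, cols).
#' @param n_frames number of frames in the series (>= 2).
#' @param pixel_size_nm physical pixel size in nanometres.
#' @param frame_interval_ms time between consecutive frames in milliseconds.
#' @param n_objects number of tracked (vesicle-channel) objects.
#' @param motile_speed_um_s directed speed during motile states, in um/s.
#' @param bound_dwell_s mean of the exponential bound-state duration, seconds.
#' @param free_dwell_s mean of the exponential motile-state duration, seconds.
#' @param localization_jitter_px sd of the positional jitter of bound objects.
#' @param heading_sd_rad per-frame sd of the motile heading (angular diffusion).
#' @param capture_radius_px distance at which a motile object whose sojourn
#'   clock has expired binds to a filament it encounters; keeps trajectories
#'   continuous (objects travel to a filament rather than jumping onto one).
#' @param n_filaments number of filaments in the binding field.
#' @param filament_persistence sd (radians) of the per-step heading change of a
#'   filament polyline; smaller values give straighter filaments.
#' @param psf_sigma_px Gaussian PSF width of vesicle-channel spots, pixels.
#' @param spot_amplitude peak amplitude of an unbleached vesicle spot (counts).
#' @param background constant background level (counts).
#' @param read_noise_sd sd of the additive Gaussian read noise (counts).
#' @param bleach_tau_frames exponential photobleaching time constant, frames.
#' @param ref_channel list configuring reference-channel objects:
#'   `count` (maximum number of reference objects), `radius_px` (association
#'   radius used for ground-truth intervals), `coloc_fraction` (target fraction
#'   of vesicle object-frames lying within the association radius of a
#'   reference object), `psf_sigma_px`, `amplitude`, `drift_sd_px` (per-frame
#'   sd of the slow random-walk drift of reference objects).
#' @param seed integer seed; fixed seed gives bit-identical ground truth and
#'   movies.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [preset_control()], [preset_septin_depleted()], [simulate_movie()]
#' @export
sim_config <- function(field_size_px = c(128L, 128L),
                       n_frames = 600L,
                       pixel_size_nm = 143,
                       frame_interval_ms = 154,
                       n_objects = 12L,
                       motile_speed_um_s = 1.0,
                       bound_dwell_s = 60,
                       free_dwell_s = 5,
                       localization_jitter_px = 0.3,
                       heading_sd_rad = 0.2,
                       capture_radius_px = 1.5,
                       n_filaments = 8L,
                       filament_persistence = 0.15,
                       psf_sigma_px = 1.3,
                       spot_amplitude = 500,
                       background = 100,
                       read_noise_sd = 2,
                       bleach_tau_frames = 600,
                       ref_channel = list(),
                       seed = 1L) {
  ref_defaults <- list(count = 25L, radius_px = 3, coloc_fraction = 0.5,
                       psf_sigma_px = 2.5, amplitude = 200, drift_sd_px = 0.02)
  stopifnot(is.list(ref_channel))
  ref <- utils::modifyList(ref_defaults, ref_channel)

  cfg <- list(
    field_size_px = as.integer(field_size_px),
    n_frames = as.integer(n_frames),
    pixel_size_nm = as.numeric(pixel_size_nm),
    frame_interval_ms = as.numeric(frame_interval_ms),
    n_objects = as.integer(n_objects),
    motile_speed_um_s = as.numeric(motile_speed_um_s),
    bound_dwell_s = as.numeric(bound_dwell_s),
    free_dwell_s = as.numeric(free_dwell_s),
    localization_jitter_px = as.numeric(localization_jitter_px),
    heading_sd_rad = as.numeric(heading_sd_rad),
    capture_radius_px = as.numeric(capture_radius_px),
    n_filaments = as.integer(n_filaments),
    filament_persistence = as.numeric(filament_persistence),
    psf_sigma_px = as.numeric(psf_sigma_px),
    spot_amplitude = as.numeric(spot_amplitude),
    background = as.numeric(background),
    read_noise_sd = as.numeric(read_noise_sd),
    bleach_tau_frames = as.numeric(bleach_tau_frames),
    ref_channel = ref,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    if (length(field_size_px) != 2L || any(field_size_px < 8L))
      stop("field_size_px must be two integers >= 8", call. = FALSE)
    if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
    if (pixel_size_nm <= 0 || frame_interval_ms <= 0)
      stop("pixel_size_nm and frame_interval_ms must be positive", call. = FALSE)
    if (n_objects < 0L) stop("n_objects must be >= 0", call. = FALSE)
    if (motile_speed_um_s <= 0) stop("motile_speed_um_s must be positive", call. = FALSE)
    if (bound_dwell_s <= 0 || free_dwell_s <= 0)
      stop("state dwell means must be positive", call. = FALSE)
    if (localization_jitter_px < 0) stop("localization_jitter_px must be >= 0", call. = FALSE)
    if (capture_radius_px <= 0) stop("capture_radius_px must be positive", call. = FALSE)
    if (n_filaments < 0L) stop("n_filaments must be >= 0", call. = FALSE)
    if (psf_sigma_px <= 0) stop("psf_sigma_px must be positive", call. = FALSE)
    if (spot_amplitude <= 0 || background < 0 || read_noise_sd < 0)
      stop("photometry parameters out of range", call. = FALSE)
    if (bleach_tau_frames <= 0) stop("bleach_tau_frames must be positive", call. = FALSE)
    if (ref_channel$coloc_fraction < 0 || ref_channel$coloc_fraction > 1)
      stop("ref_channel$coloc_fraction must lie in [0, 1]", call. = FALSE)
    if (ref_channel$count < 0L) stop("ref_channel$count must be >= 0", call. = FALSE)
    if (ref_channel$radius_px <= 0) stop("ref_channel$radius_px must be positive", call. = FALSE)
  })
  config
}

#' Control-condition preset
#'
#' Acquisition and motion parameters emulating the control condition of the
#' live-imaging experiments: 600-frame series at 475 ms between frames
#' (the regime of the trajectory/association acquisitions), 143 nm pixels,
#' directed motile speed 1 um/s, mean filament-bound dwell 60 s (~1 min
#' association), high signal-to-noise spots.
#'
#' @param ... overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
preset_control <- function(...) {
  args <- utils::modifyList(list(frame_interval_ms = 475,
                                 motile_speed_um_s = 1.0,
                                 bound_dwell_s = 60,
                                 free_dwell_s = 5),
                            list(...))
  do.call(sim_config, args)
}

#' Septin-depleted-condition preset
#'
#' As [preset_control()] but with the perturbed association dynamics observed
#' upon septin depletion: brief coat association (mean bound dwell 25 s,
#' within the reported 20-30 s range) and longer motile excursions, at the
#' same directed speed.
#'
#' @param ... overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
preset_septin_depleted <- function(...) {
  args <- utils::modifyList(list(frame_interval_ms = 475,
                                 motile_speed_um_s = 1.0,
                                 bound_dwell_s = 25,
                                 free_dwell_s = 8),
                            list(...))
  do.call(sim_config, args)
}

#' Movie calibration metadata
#'
#' @param pixel_size_nm physical pixel size, nanometres (> 0).
#' @param frame_interval_ms time between consecutive frames, milliseconds (> 0).
#' @param n_frames number of frames.
#' @param channel_names character vector of channel labels.
#' @return A list of class `movie_metadata`.
#' @export
movie_metadata <- function(pixel_size_nm, frame_interval_ms, n_frames,
                           channel_names = "channel1") {
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be positive", call. = FALSE)
  if (frame_interval_ms <= 0) stop("frame_interval_ms must be positive", call. = FALSE)
  structure(list(pixel_size_nm = as.numeric(pixel_size_nm),
                 frame_interval_ms = as.numeric(frame_interval_ms),
                 n_frames = as.integer(n_frames),
                 channel_names = as.character(channel_names)),
            class = "movie_metadata")
}

# px/frame equivalent of the configured motile speed
speed_px_per_frame <- function(config) {
  config$motile_speed_um_s * config$frame_interval_ms / config$pixel_size_nm
}
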