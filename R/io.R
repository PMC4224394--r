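#' Write a movie as a multi-page TIFF with sidecar metadata
#'
#' Pages are ordered frame-major, channel-minor (T -> C -> Y -> X): for each
#' frame, one page per channel in the order of `movie$channels`. Intensities
#' are stored as 16-bit unsigned integers (values clamped to [0, 65535] and
#' rounded). A YAML sidecar records the calibration metadata, the channel
#' names and, when supplied, the full simulation configuration and seed.
#'
#' @param movie an `endo_movie`.
#' @param path output TIFF file path.
#' @param metadata_path sidecar path; default replaces the TIFF extension with
#'   `.yaml`.
#' @param config optional [sim_config()] recorded verbatim in the sidecar.
#' @return Invisibly, the TIFF path.
#' @export
write_movie_tiff <- function(movie, path,
                             metadata_path = sub("\\.tiff?$", ".yaml", path),
                             config = NULL) {
  stopifnot(inherits(movie, "endo_movie"))
  md <- movie$metadata
  n <- md$n_frames
  pages <- vector("list", n * length(movie$channels))
  p <- 0L
  for (k in seq_len(n)) {
    for (ch in seq_along(movie$channels)) {
      p <- p + 1L
      m <- round(movie$channels[[ch]][, , k])
      m[m < 0] <- 0
      m[m > 65535] <- 65535
      pages[[p]] <- m / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)

  meta <- list(pixel_size_nm = md$pixel_size_nm,
               frame_interval_ms = md$frame_interval_ms,
               n_frames = md$n_frames,
               channel_names = as.list(md$channel_names))
  if (!is.null(config)) {
    meta$seed <- config$seed
    meta$sim_config <- unclass(config)
  }
  yaml::write_yaml(meta, metadata_path)
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' Also accepts plain single-channel stacks (one page per frame) when the
#' sidecar is absent; calibration must then be supplied explicitly.
#'
#' @param path TIFF file path.
#' @param metadata_path sidecar YAML path; default replaces the extension.
#' @param pixel_size_nm,frame_interval_ms calibration used when no sidecar
#'   exists.
#' @param channel_names channel labels used when no sidecar exists; their
#'   number determines how pages are de-interleaved.
#' @return An `endo_movie`.
#' @export
read_movie_tiff <- function(path,
                            metadata_path = sub("\\.tiff?$", ".yaml", path),
                            pixel_size_nm = NULL, frame_interval_ms = NULL,
                            channel_names = "channel1") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (file.exists(metadata_path)) {
    meta <- yaml::read_yaml(metadata_path)
    pixel_size_nm <- meta$pixel_size_nm
    frame_interval_ms <- meta$frame_interval_ms
    channel_names <- unlist(meta$channel_names)
  } else if (is.null(pixel_size_nm) || is.null(frame_interval_ms)) {
    stop("no sidecar metadata found; supply pixel_size_nm and frame_interval_ms",
         call. = FALSE)
  }
  n_ch <- length(channel_names)
  if (length(pages) %% n_ch != 0L)
    stop("page count ", length(pages), " is not a multiple of the channel count ",
         n_ch, call. = FALSE)
  n <- length(pages) %/% n_ch
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  channels <- stats::setNames(vector("list", n_ch), channel_names)
  for (ch in seq_len(n_ch)) {
    arr <- array(0, dim = c(ny, nx, n))
    for (k in seq_len(n)) arr[, , k] <- pages[[(k - 1L) * n_ch + ch]] * 65535
    channels[[ch]] <- arr
  }
  structure(list(channels = channels,
                 metadata = movie_metadata(pixel_size_nm, frame_interval_ms,
                                           n, channel_names)),
            class = "endo_movie")
}

#' Write ground truth as CSV tables
#'
#' Two files: `<prefix>_tracks.csv` (object_id, frame, x_px, y_px, state) and
#' `<prefix>_associations.csv` (object_id, ref_id, start_frame, end_frame);
#' reference positions go to `<prefix>_refs.csv` when present.
#'
#' @param truth a `ground_truth`.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_ground_truth_csv <- function(truth, prefix) {
  stopifnot(inherits(truth, "ground_truth"))
  paths <- c(tracks = paste0(prefix, "_tracks.csv"),
             associations = paste0(prefix, "_associations.csv"),
             refs = paste0(prefix, "_refs.csv"))
  utils::write.csv(truth$true_tracks, paths["tracks"], row.names = FALSE)
  utils::write.csv(truth$association_intervals, paths["associations"],
                   row.names = FALSE)
  utils::write.csv(truth$ref_positions, paths["refs"], row.names = FALSE)
  invisible(paths)
}
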