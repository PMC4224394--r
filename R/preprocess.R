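#' Photobleaching correction by intensity normalization
#'
#' Rescales every frame multiplicatively so that its mean intensity equals a
#' reference level, per channel. With `reference = "first_frame"` the level is
#' the mean of frame 1; with `"global_median"` it is the median of the
#' per-frame means. On a noiselessly bleaching movie the corrected frame means
#' are constant over time (to floating-point precision).
#'
#' @param movie an `endo_movie`, or a single ny x nx x T array.
#' @param reference `"first_frame"` (default) or `"global_median"`.
#' @return Object of the same shape as `movie` with corrected intensities.
#' @export
bleach_correct <- function(movie, reference = c("first_frame", "global_median")) {
  reference <- match.arg(reference)
  if (inherits(movie, "endo_movie")) {
    movie$channels <- lapply(movie$channels, bleach_correct_array,
                             reference = reference)
    return(movie)
  }
  bleach_correct_array(movie, reference)
}

bleach_correct_array <- function(arr, reference) {
  stopifnot(length(dim(arr)) == 3L)
  n <- dim(arr)[3]
  levels <- vapply(seq_len(n), function(k) mean(arr[, , k]), numeric(1))
  bad <- which(levels <= 0)
  if (length(bad) > 0L)
    stop("frame ", bad[1] - 1L, " has non-positive mean intensity; ",
         "cannot normalize", call. = FALSE)
  ref_level <- switch(reference,
                      first_frame = levels[1],
                      global_median = stats::median(levels))
  scale <- ref_level / levels
  for (k in seq_len(n)) arr[, , k] <- arr[, , k] * scale[k]
  arr
}

#' Isotropic undecimated a-trous wavelet decomposition
#'
#' Decomposes a 2-D image into `n_scales` detail planes plus a smooth
#' residual using the separable B3-spline kernel (1,4,6,4,1)/16 with
#' `2^(j-1) - 1` zeros inserted between taps at scale `j` and mirror boundary
#' handling. The scheme is additive: the detail planes and the residual sum
#' back to the input exactly.
#'
#' @param image 2-D numeric matrix with finite entries.
#' @param n_scales number of detail scales (>= 1).
#' @return List with `details` (list of `n_scales` matrices) and `residual`.
#' @export
atrous_decompose <- function(image, n_scales = 3L) {
  stopifnot(is.matrix(image), all(is.finite(image)), n_scales >= 1L)
  max_shift <- 2L * 2L^(n_scales - 1L)
  if (max_shift > min(dim(image)) - 1L)
    stop("n_scales too large for image size: kernel reach ", max_shift,
         " exceeds smallest dimension ", min(dim(image)), call. = FALSE)
  details <- vector("list", n_scales)
  smooth <- image
  for (j in seq_len(n_scales)) {
    h <- 2L^(j - 1L)
    next_smooth <- b3_smooth(smooth, h)
    details[[j]] <- smooth - next_smooth
    smooth <- next_smooth
  }
  list(details = details, residual = smooth)
}

# Separable B3-spline smoothing with hole spacing h and whole-sample mirror
# boundary (edge pixel not duplicated).
b3_smooth <- function(image, h) {
  w <- c(1, 4, 6, 4, 1) / 16
  offs <- c(-2L, -1L, 0L, 1L, 2L) * h
  smooth_rows <- function(m) {  # along columns (y direction)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(offs)) {
      idx <- seq_len(n) + offs[t]
      idx <- mirror_index(idx, n)
      out <- out + w[t] * m[idx, , drop = FALSE]
    }
    out
  }
  t(smooth_rows(t(smooth_rows(image))))
}

# Whole-sample mirror: index i reflects about 1 and n without repeating edges.
mirror_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  j <- (idx - 1L) %% period
  j <- ifelse(j >= n, period - j, j)
  j + 1L
}

#' Wavelet spot detection with sub-pixel centroids
#'
#' Thresholds selected a-trous detail planes at `k_mad` times a robust
#' (1.4826 x MAD) per-plane noise estimate, takes the conjunction of the
#' per-scale masks, labels connected components, and keeps components of at
#' least `min_area_px` pixels. Touching spots (two objects closer than the
#' mask smearing scale) form a single connected component; with
#' `split_touching = TRUE` (default) components are split at intensity
#' watershed lines of the reconstruction, with a noise-scaled tolerance so a
#' single noisy spot is not fragmented. Each component becomes one detection
#' whose sub-pixel position is the intensity-weighted centroid over the
#' background-subtracted image (the sum of the selected detail planes, floored
#' at zero) and whose intensity is the component sum of that image.
#'
#' Coordinates are 0-based, pixel-center; `x_px` is the column and `y_px` the
#' row.
#'
#' @param image 2-D numeric matrix (a single frame, ideally bleach-corrected).
#' @param n_scales scales in the decomposition.
#' @param detection_scales which detail planes enter the detection mask.
#' @param k_mad threshold in robust noise sd units.
#' @param min_area_px minimum component area in pixels.
#' @param split_touching split merged components at watershed lines of the
#'   reconstructed intensity (default `TRUE`).
#' @return data.frame with columns `x_px`, `y_px`, `intensity`, `area_px`
#'   (zero rows when nothing is detected).
#' @export
detect_spots <- function(image, n_scales = 3L, detection_scales = c(2L, 3L),
                         k_mad = 3, min_area_px = 2L, split_touching = TRUE) {
  stopifnot(all(detection_scales >= 1L), all(detection_scales <= n_scales))
  dec <- atrous_decompose(image, n_scales)
  mask <- matrix(TRUE, nrow(image), ncol(image))
  recon <- matrix(0, nrow(image), ncol(image))
  sigma2_sum <- 0
  for (j in detection_scales) {
    d <- dec$details[[j]]
    sigma <- stats::mad(d)  # 1.4826 * median absolute deviation
    thr <- k_mad * sigma
    mask <- mask & (d > thr)
    recon <- recon + d
    sigma2_sum <- sigma2_sum + sigma^2
  }
  recon[recon < 0] <- 0
  empty <- data.frame(x_px = numeric(), y_px = numeric(),
                      intensity = numeric(), area_px = integer())
  if (!any(mask)) return(empty)

  if (split_touching) {
    # saddles shallower than the detection threshold are treated as noise
    tol <- k_mad * sqrt(sigma2_sum)
    labels <- EBImage::imageData(
      EBImage::watershed(EBImage::Image(recon * mask), tolerance = tol, ext = 1L))
  } else {
    labels <- EBImage::bwlabel(mask * 1L)
  }
  n_comp <- max(labels)
  if (n_comp == 0L) return(empty)
  idx <- which(labels > 0)
  comp <- labels[idx]
  rows <- (idx - 1L) %% nrow(image) + 1L
  cols <- (idx - 1L) %/% nrow(image) + 1L
  wts <- recon[idx]

  area <- tabulate(comp, n_comp)
  wsum <- tapply_sum(wts, comp, n_comp)
  keep <- which(area >= min_area_px & wsum > 0)
  if (length(keep) == 0L) return(empty)
  xs <- tapply_sum(wts * (cols - 1L), comp, n_comp)
  ys <- tapply_sum(wts * (rows - 1L), comp, n_comp)
  out <- data.frame(x_px = xs[keep] / wsum[keep],
                    y_px = ys[keep] / wsum[keep],
                    intensity = wsum[keep],
                    area_px = area[keep])
  # deterministic output order
  out <- out[order(out$y_px, out$x_px), , drop = FALSE]
  rownames(out) <- NULL
  out
}

tapply_sum <- function(x, group, n_groups) {
  out <- numeric(n_groups)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Detect spots in every frame of a movie channel
#'
#' @param movie an `endo_movie` or ny x nx x T array.
#' @param channel channel name or index (ignored for arrays).
#' @param correct_bleach apply [bleach_correct()] to the channel first.
#' @param ... forwarded to [detect_spots()].
#' @return data.frame with columns `frame` (0-based), `x_px`, `y_px`,
#'   `intensity`, `area_px`.
#' @export
detect_movie <- function(movie, channel = 1L, correct_bleach = TRUE, ...) {
  arr <- if (inherits(movie, "endo_movie")) movie$channels[[channel]] else movie
  stopifnot(length(dim(arr)) == 3L)
  if (correct_bleach) arr <- bleach_correct_array(arr, "first_frame")
  n <- dim(arr)[3]
  out <- vector("list", n)
  for (k in seq_len(n)) {
    d <- detect_spots(arr[, , k], ...)
    if (nrow(d) > 0L) out[[k]] <- cbind(frame = k - 1L, d)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
                      intensity = numeric(), area_px = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
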