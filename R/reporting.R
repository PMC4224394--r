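#' Single-factor (one-way) analysis of variance
#'
#' Classical fixed-effects one-way ANOVA, as produced by spreadsheet
#' "ANOVA: Single Factor": F = MS_between / MS_within with the p value from
#' the F distribution. Implemented on [stats::lm()]/[stats::anova()].
#'
#' @param groups list of >= 2 numeric vectors, each with n >= 2.
#' @return List of class `anova_result`: `F`, `df_between`, `df_within`, `p`.
#' @export
anova_single_factor <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L)) stop("every group needs n >= 2", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), ns))
  tab <- stats::anova(stats::lm(y ~ g))
  f <- tab$`F value`[1]
  # identical groups: SS_between = 0 exactly -> F = 0, p = 1
  if (!is.finite(f)) f <- 0
  p <- stats::pf(f, tab$Df[1], tab$Df[2], lower.tail = FALSE)
  structure(list(F = f, df_between = tab$Df[1], df_within = tab$Df[2], p = p),
            class = "anova_result")
}

#' Total detected-object intensity per time point
#'
#' Per frame, the sum of detection intensities, optionally restricted to a
#' rectangular region (a per-cell window) and optionally normalized to the
#' first frame.
#'
#' @param detections data.frame with `frame`, `x_px`, `y_px`, `intensity`.
#' @param n_frames length of the series; frames with no detections report 0.
#' @param region optional `c(xmin, xmax, ymin, ymax)` in pixel coordinates.
#' @param normalize divide the series by its frame-0 value (default FALSE).
#' @return data.frame with `frame`, `total_intensity`.
#' @export
intensity_time_course <- function(detections, n_frames, region = NULL,
                                  normalize = FALSE) {
  det <- detections
  if (!is.null(region)) {
    stopifnot(length(region) == 4L)
    det <- det[det$x_px >= region[1] & det$x_px <= region[2] &
               det$y_px >= region[3] & det$y_px <= region[4], , drop = FALSE]
  }
  total <- numeric(n_frames)
  if (nrow(det) > 0L) {
    s <- rowsum(det$intensity, det$frame)
    total[as.integer(rownames(s)) + 1L] <- s[, 1]
  }
  if (normalize) {
    if (total[1] <= 0)
      stop("cannot normalize: frame 0 total intensity is not positive",
           call. = FALSE)
    total <- total / total[1]
  }
  data.frame(frame = 0:(n_frames - 1L), total_intensity = total)
}

#' Aggregate replicate series into mean and standard deviation
#'
#' Aligns replicate time courses on a common time grid (values are assigned
#' to the nearest grid point of the first replicate when grids differ) and
#' reports the per-point mean, sample standard deviation (n - 1 denominator,
#' the spreadsheet convention) and replicate count, computed over non-missing
#' values only.
#'
#' @param replicates list of >= 1 data.frames with columns `time` and `value`.
#' @param label condition label attached to the output.
#' @return data.frame of class `condition_series`: `condition`, `time`,
#'   `mean`, `sd`, `n`.
#' @export
aggregate_conditions <- function(replicates, label = "condition") {
  if (!is.list(replicates) || length(replicates) == 0L)
    stop("need at least one replicate", call. = FALSE)
  stopifnot(all(vapply(replicates, function(r)
    all(c("time", "value") %in% names(r)), logical(1))))
  grid <- sort(unique(replicates[[1]]$time))
  mat <- sapply(replicates, function(r) {
    idx <- vapply(r$time, function(t) which.min(abs(grid - t)), integer(1))
    v <- rep(NA_real_, length(grid))
    v[idx] <- r$value
    v
  })
  mat <- matrix(mat, nrow = length(grid))
  out <- data.frame(
    condition = label,
    time = grid,
    mean = apply(mat, 1L, function(v) mean(v[!is.na(v)])),
    sd = apply(mat, 1L, function(v) stats::sd(v[!is.na(v)])),
    n = apply(mat, 1L, function(v) sum(!is.na(v)))
  )
  class(out) <- c("condition_series", class(out))
  out
}

#' Per-time-point ANOVA between conditions
#'
#' For each shared time point, a one-way ANOVA across conditions over their
#' replicate values. No multiple-testing correction is applied across time
#' points; the output notes this in its `adjustment` attribute.
#'
#' @param condition_replicates named list: per condition, a list of replicate
#'   data.frames (`time`, `value`).
#' @return data.frame with `time`, `F`, `df_between`, `df_within`, `p`.
#' @export
compare_conditions <- function(condition_replicates) {
  stopifnot(is.list(condition_replicates), length(condition_replicates) >= 2L)
  times <- Reduce(intersect, lapply(condition_replicates, function(reps)
    Reduce(intersect, lapply(reps, function(r) r$time))))
  rows <- lapply(times, function(t) {
    groups <- lapply(condition_replicates, function(reps)
      vapply(reps, function(r) r$value[match(t, r$time)], numeric(1)))
    groups <- lapply(groups, function(g) g[!is.na(g)])
    if (any(vapply(groups, length, integer(1)) < 2L)) return(NULL)
    a <- anova_single_factor(groups)
    data.frame(time = t, F = a$F, df_between = a$df_between,
               df_within = a$df_within, p = a$p)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(time = numeric(), F = numeric(), df_between = integer(),
                      df_within = integer(), p = numeric())
  attr(out, "adjustment") <- "none"
  out
}
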