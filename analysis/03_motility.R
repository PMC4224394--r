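#!/usr/bin/env Rscript
# Step 3: per-step motility classification and physical track statistics.
#
# Applies the 3-pixel displacement criterion (strict: a step moves only when
# its displacement is >= 3 px between consecutive frames) to every retained
# track and summarizes path length, net displacement, immobile fraction and
# mean motile-step speed per condition. Writes results/tables/motility.csv
# and a trajectory overlay figure.

library(endotrack)

tab_dir <- file.path("results", "tables")
fig_dir <- file.path("results", "figures")
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

track_files <- list.files(tab_dir, pattern = "_tracks\\.csv$", full.names = TRUE)
if (length(track_files) == 0L) stop("run analysis/02_detect_track.R first")

md <- movie_metadata(143, 475, 600, c("vesicle", "reference"))
all_metrics <- list()
for (path in track_files) {
  stem <- sub("_tracks\\.csv$", "", basename(path))
  cond <- sub("_rep[0-9]+$", "", stem)
  tracks <- utils::read.csv(path)
  if (nrow(tracks) == 0L) next
  mot <- motility_summary(tracks, md, threshold_px = 3.0)
  m <- mot$metrics
  m$condition <- cond
  m$replicate <- stem
  all_metrics[[stem]] <- m
}
metrics <- do.call(rbind, all_metrics)
utils::write.csv(metrics, file.path(tab_dir, "motility.csv"), row.names = FALSE)

for (cond in unique(metrics$condition)) {
  mm <- metrics[metrics$condition == cond, ]
  message(sprintf(
    "%s: %d tracks | path length %.2f um | immobile fraction %.2f | motile speed %.2f um/s",
    cond, nrow(mm), mean(mm$path_length_um), mean(mm$immobile_fraction),
    mean(mm$mean_motile_speed_um_s, na.rm = TRUE)))
}

# depletion shifts time from the filament-bound to the motile state, so the
# immobile fraction separates the conditions more sharply than per-track
# path length (control tracks also persist longer)
for (stat in c("immobile_fraction", "path_length_um")) {
  a <- anova_single_factor(split(metrics[[stat]], metrics$condition))
  message(sprintf("%s ANOVA: F = %.2f (df %d, %d), p = %.3g",
                  stat, a$F, a$df_between, a$df_within, a$p))
}

if (requireNamespace("ggplot2", quietly = TRUE)) {
  tracks <- do.call(rbind, lapply(track_files, function(p) {
    tr <- utils::read.csv(p)
    tr$condition <- sub("_rep[0-9]+.*$", "", basename(p))
    tr$uid <- paste(basename(p), tr$track_id)
    tr
  }))
  gp <- ggplot2::ggplot(tracks, ggplot2::aes(x_px, y_px, group = uid)) +
    ggplot2::geom_path(linewidth = 0.2, alpha = 0.6, colour = "darkgreen") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Tracked object trajectories",
                  x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(fig_dir, "trajectories.pdf"), gp,
                  width = 8, height = 4)
  message("Wrote ", file.path(fig_dir, "trajectories.pdf"))
}
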