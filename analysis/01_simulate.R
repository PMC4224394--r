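#!/usr/bin/env Rscript
# Step 1: generate the two study conditions as synthetic acquisitions.
#
# Control cells: AP-3-like coats dwell ~1 min on their target compartments
# and make short (~5 um) excursions at 1 um/s. Septin-depleted cells: brief
# association (25 s) and longer excursions. Both are imaged as 600-frame
# two-channel series at 475 ms/frame, 143 nm pixels. Movies go to scratch/
# (they are large and reproducible); ground truth goes with them.

library(endotrack)

out_dir <- file.path("scratch", "movies")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

conditions <- list(
  control = function(seed) preset_control(seed = seed),
  depleted = function(seed) preset_septin_depleted(seed = seed)
)
seeds <- c(101L, 102L, 103L)   # three replicates per condition

for (cond in names(conditions)) {
  for (r in seq_along(seeds)) {
    cfg <- conditions[[cond]](seeds[r])
    sim <- simulate_movie(cfg)
    stem <- file.path(out_dir, sprintf("%s_rep%d", cond, r))
    write_movie_tiff(sim$movie, paste0(stem, ".tif"), config = cfg)
    write_ground_truth_csv(sim$truth, stem)
    n_assoc <- nrow(sim$truth$association_intervals)
    message(sprintf("%s rep %d: %d objects, %d frames, %d true association intervals",
                    cond, r, cfg$n_objects, cfg$n_frames, n_assoc))
  }
}
message("Movies and ground truth written under ", out_dir)
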