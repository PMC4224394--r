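#!/usr/bin/env Rscript
# Step 5: replicate aggregation and condition comparison.
#
# Aggregates the per-replicate colocalization time courses into mean +/- SD
# per condition, runs a per-time-point single-factor ANOVA between
# conditions (no multiple-testing correction, noted in the output), and
# writes the tidy summary table and a time-course figure.

library(endotrack)

tab_dir <- file.path("results", "tables")
fig_dir <- file.path("results", "figures")
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

tc <- utils::read.csv(file.path(tab_dir, "coloc_timecourse.csv"))

by_cond <- split(tc, tc$condition)
agg <- do.call(rbind, lapply(names(by_cond), function(cond) {
  reps <- lapply(split(by_cond[[cond]], by_cond[[cond]]$replicate), function(r)
    data.frame(time = r$time_s, value = r$fraction))
  aggregate_conditions(reps, cond)
}))
utils::write.csv(agg, file.path(tab_dir, "condition_summary.csv"),
                 row.names = FALSE)

cond_reps <- lapply(by_cond, function(d)
  lapply(split(d, d$replicate), function(r)
    data.frame(time = r$time_s, value = r$fraction)))
anova_tab <- compare_conditions(cond_reps)
anova_tab$adjustment <- "none"
utils::write.csv(anova_tab, file.path(tab_dir, "condition_anova.csv"),
                 row.names = FALSE)

message("Per-time-point ANOVA (control vs depleted colocalization):")
for (i in seq_len(nrow(anova_tab)))
  message(sprintf("  t = %5.1f s  F = %6.2f  p = %.3g",
                  anova_tab$time[i], anova_tab$F[i], anova_tab$p[i]))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  gp <- ggplot2::ggplot(agg, ggplot2::aes(time, mean, colour = condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sd, ymax = mean + sd,
                                      fill = condition),
                         alpha = 0.2, colour = NA) +
    ggplot2::labs(title = "Coat-compartment colocalization over time",
                  subtitle = "mean +/- SD over replicates",
                  x = "time (s)", y = "colocalized fraction") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(fig_dir, "coloc_timecourse.pdf"), gp,
                  width = 7, height = 4)
  message("Wrote ", file.path(fig_dir, "coloc_timecourse.pdf"))
}
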