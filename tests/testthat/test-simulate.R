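test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_frames = 1L), "n_frames")
  expect_error(sim_config(motile_speed_um_s = 0), "speed")
  expect_error(sim_config(bound_dwell_s = -1), "dwell")
  expect_error(sim_config(ref_channel = list(coloc_fraction = 1.5)),
               "coloc_fraction")
  expect_error(sim_config(field_size_px = c(-4, 10)), "field_size_px")
})

test_that("presets encode the two imaging conditions", {
  ctrl <- preset_control()
  dep <- preset_septin_depleted()
  expect_equal(ctrl$motile_speed_um_s, 1.0)
  expect_equal(ctrl$bound_dwell_s, 60)
  expect_equal(dep$bound_dwell_s, 25)
  expect_true(dep$bound_dwell_s >= 20 && dep$bound_dwell_s <= 30)
  expect_equal(ctrl$frame_interval_ms, dep$frame_interval_ms)
  expect_equal(ctrl$pixel_size_nm, 143)
})

test_that("filament field: empty case, determinism, bounds", {
  cfg0 <- sim_config(n_filaments = 0L, seed = 4L)
  expect_length(make_filament_field(cfg0)$filaments, 0L)

  cfg <- sim_config(n_filaments = 5L, field_size_px = c(128L, 128L), seed = 4L)
  f1 <- make_filament_field(cfg)
  f2 <- make_filament_field(cfg)
  expect_identical(f1, f2)
  expect_length(f1$filaments, 5L)
  for (poly in f1$filaments) {
    expect_gte(nrow(poly), 2L)
    expect_true(all(poly[, 1] >= 0 & poly[, 1] < 128))
    expect_true(all(poly[, 2] >= 0 & poly[, 2] < 128))
  }
})

test_that("motile-only proxy recovers the configured step length", {
  # bound probability ~0: mean true step ~ speed * dt / pixel size
  cfg <- sim_config(n_frames = 400L, n_objects = 8L, free_dwell_s = 1e9,
                    ref_channel = list(coloc_fraction = 0), seed = 11L)
  tr <- simulate_tracks(cfg)$true_tracks
  expect_true(all(tr$state == "motile"))
  steps <- unlist(lapply(split(tr, tr$object_id), function(d)
    sqrt(diff(d$x_px)^2 + diff(d$y_px)^2)))
  expected <- 1000 * 0.154 / 143   # 1 um/s at 154 ms and 143 nm -> 1.0769 px
  expect_equal(mean(steps), expected, tolerance = 0.02)
})

test_that("bound-only proxy stays within the localization jitter", {
  cfg <- sim_config(n_frames = 300L, n_objects = 6L, bound_dwell_s = 1e9,
                    ref_channel = list(coloc_fraction = 0), seed = 12L)
  tr <- simulate_tracks(cfg)$true_tracks
  expect_true(all(tr$state == "bound"))
  steps <- unlist(lapply(split(tr, tr$object_id), function(d)
    sqrt(diff(d$x_px)^2 + diff(d$y_px)^2)))
  # steps are differences of two N(0, jitter) jitters per axis, i.e.
  # Rayleigh with scale sqrt(2)*jitter: P(step > 4*jitter) = exp(-4) ~ 1.8%
  expect_gt(mean(steps <= 4 * cfg$localization_jitter_px), 0.96)
})

test_that("completed bound-state durations recover the exponential mean", {
  # window >> mean dwell so truncation of completed intervals is negligible
  cfg <- sim_config(n_frames = 4000L, n_objects = 10L, bound_dwell_s = 20,
                    free_dwell_s = 5, frame_interval_ms = 475,
                    field_size_px = c(96L, 96L),
                    ref_channel = list(coloc_fraction = 0), seed = 13L)
  bi <- simulate_tracks(cfg)$bound_intervals
  comp <- bi[bi$start_frame > 0 & bi$end_frame < cfg$n_frames - 1L, ]
  dur <- (comp$end_frame - comp$start_frame + 1L) * 0.475
  expect_gt(nrow(comp), 200L)
  expect_equal(mean(dur), 20, tolerance = 0.15)
})

test_that("ground truth respects its structural invariants", {
  cfg <- preset_control(n_frames = 150L, n_objects = 6L, seed = 14L)
  gt <- simulate_tracks(cfg)
  expect_true(all(is.finite(gt$true_tracks$x_px)))
  expect_true(all(is.finite(gt$true_tracks$y_px)))
  ai <- gt$association_intervals
  expect_true(all(ai$start_frame <= ai$end_frame))
  expect_true(all(ai$start_frame >= 0 & ai$end_frame < cfg$n_frames))
  # intervals non-overlapping per object
  for (obj in unique(ai$object_id)) {
    iv <- ai[ai$object_id == obj, ]
    iv <- iv[order(iv$start_frame), ]
    if (nrow(iv) > 1L)
      expect_true(all(iv$start_frame[-1L] > iv$end_frame[-nrow(iv)]))
  }
})

test_that("configured coloc_fraction is realized without bias", {
  # Within one acquisition the within-radius indicator is autocorrelated over
  # the ~1 min dwell, so a single movie's fraction has a sampling sd of
  # several percent. Unbiasedness is therefore checked across independent
  # acquisitions against the empirical standard error.
  fr <- vapply(1:8, function(s) {
    cfg <- preset_control(n_frames = 250L, n_objects = 10L,
                          ref_channel = list(coloc_fraction = 0.5),
                          seed = 150L + s)
    gt <- simulate_tracks(cfg)
    tt <- gt$true_tracks
    rp <- gt$ref_positions
    hit <- vapply(split(tt, tt$frame), function(d) {
      r <- rp[rp$frame == d$frame[1], ]
      d2 <- outer(d$x_px, r$x_px, "-")^2 + outer(d$y_px, r$y_px, "-")^2
      sum(apply(d2, 1, min) <= cfg$ref_channel$radius_px^2)
    }, numeric(1))
    sum(hit) / nrow(tt)
  }, numeric(1))
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.5), 3 * se + 0.015)
})

test_that("fixed seed gives bit-identical truth and movie", {
  cfg <- preset_control(n_frames = 40L, n_objects = 4L, seed = 16L)
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$movie$channels, b$movie$channels)
})

test_that("rendering: background-only mean and bleach-constant recovery", {
  cfg0 <- sim_config(n_frames = 30L, n_objects = 0L,
                     ref_channel = list(coloc_fraction = 0),
                     field_size_px = c(48L, 48L),
                     bleach_tau_frames = 1e9, seed = 17L)
  mv <- simulate_movie(cfg0)$movie
  m <- mean(mv$channels$vesicle)
  se <- sqrt(cfg0$background / prod(dim(mv$channels$vesicle)))
  expect_lt(abs(m - cfg0$background), 3 * se + 0.05)

  # noiseless exponential bleach: least-squares fit on log frame means
  cfg <- sim_config(n_frames = 120L, n_objects = 5L, bleach_tau_frames = 200,
                    field_size_px = c(64L, 64L),
                    ref_channel = list(coloc_fraction = 0), seed = 18L)
  mv <- simulate_movie(cfg, noise = FALSE)$movie
  means <- apply(mv$channels$vesicle, 3, mean)
  fit <- stats::lm(log(means) ~ seq_along(means))
  tau_hat <- -1 / stats::coef(fit)[2]
  expect_equal(unname(tau_hat), 200, tolerance = 0.1)
})

test_that("a docking ramp moves the association wave to the configured peak", {
  cfg <- preset_control(n_frames = 600L, n_objects = 10L,
                        bound_dwell_s = 25, free_dwell_s = 8,
                        ref_channel = list(coloc_fraction = 0.7,
                                           ramp = list(peak_frame = 300,
                                                       sd_frames = 120)),
                        seed = 19L)
  gt <- simulate_tracks(cfg)
  tt <- gt$true_tracks
  rp <- gt$ref_positions
  tc <- coloc_time_course(tt, rp, cfg$ref_channel$radius_px,
                          movie_metadata(143, 475, 600, "a"),
                          bin_frames = 100L)
  expect_true(all(tc$fraction >= 0 & tc$fraction <= 1, na.rm = TRUE))
  peak_bin <- tc$frame_mid[which.max(tc$fraction)]
  expect_gt(peak_bin, 150)
  expect_lt(peak_bin, 480)
})
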