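md <- movie_metadata(143, 154, 600, c("vesicle", "reference"))

ref_table <- function(frames, x, y, id = 1L) {
  data.frame(ref_id = id, frame = frames, x_px = x, y_px = y)
}

test_that("object colocalization fraction: identity, disjoint, contracts", {
  a <- data.frame(x_px = c(1, 5, 9), y_px = c(1, 5, 9))
  expect_equal(object_coloc_fraction(a, a, 0.5), 1.0)
  b <- data.frame(x_px = a$x_px + 50, y_px = a$y_px)
  expect_equal(object_coloc_fraction(a, b, 3), 0.0)
  expect_true(is.na(object_coloc_fraction(a[0, ], a, 3)))
  expect_equal(object_coloc_fraction(a, b[0, ], 3), 0)
  expect_error(object_coloc_fraction(a, b, -1), "radius")
  # directional: half of A near B is not half of B near A
  a2 <- data.frame(x_px = c(0, 10), y_px = 0)
  b2 <- data.frame(x_px = c(0, 0.5, 30, 40), y_px = 0)
  expect_equal(object_coloc_fraction(a2, b2, 1), 0.5)
  expect_equal(object_coloc_fraction(b2, a2, 1), 0.5)
  b3 <- data.frame(x_px = c(0, 0.5), y_px = 0)
  expect_equal(object_coloc_fraction(b3, a2, 1), 1.0)
})

test_that("colocalization time course: identical channels and zero radius", {
  det <- do.call(rbind, lapply(0:9, function(f)
    data.frame(frame = f, x_px = c(3, 8) + 0.1 * f, y_px = 5)))
  md10 <- movie_metadata(143, 154, 10, "a")
  tc <- coloc_time_course(det, det, 3, md10, bin_frames = 2L)
  expect_equal(tc$fraction, rep(1, 5))
  expect_equal(tc$n_objects, rep(4L, 5))

  noisy <- det
  set.seed(71)
  noisy$x_px <- noisy$x_px + stats::rnorm(nrow(noisy), 0, 0.2)
  tc0 <- coloc_time_course(noisy, det, 0, md10)
  expect_true(all(tc0$fraction < 0.2))
})

test_that("association runs: full-span event, dwell arithmetic, censoring", {
  tr <- data.frame(track_id = 7L, frame = 0:9, x_px = 10, y_px = 10,
                   intensity = 1)
  refs <- ref_table(0:9, 10.5, 10)
  ev <- association_runs(tr, refs, radius_px = 3, metadata = md)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$dwell_s, 10 * 0.154)   # 1.54 s over 10 frames at 154 ms
  expect_true(ev$censored)               # truncated at both track ends
  expect_equal(ev$ref_id, 1L)
})

test_that("gap handling: broken by one frame unless max_gap_frames allows it", {
  tr <- data.frame(track_id = 1L, frame = 0:8,
                   x_px = c(10, 10, 10, 10, 50, 10, 10, 10, 10),
                   y_px = 10, intensity = 1)
  refs <- ref_table(0:8, 10, 10)
  strict <- association_runs(tr, refs, radius_px = 3, max_gap_frames = 0L,
                             metadata = md)
  expect_equal(nrow(strict), 2L)
  tolerant <- association_runs(tr, refs, radius_px = 3, max_gap_frames = 1L,
                               metadata = md)
  expect_equal(nrow(tolerant), 1L)
  expect_equal(tolerant$n_gap_frames, 1L)
})

test_that("a reference handover closes the event", {
  tr <- data.frame(track_id = 1L, frame = 0:5,
                   x_px = c(10, 10, 10, 20, 20, 20), y_px = 10, intensity = 1)
  refs <- rbind(ref_table(0:5, 10, 10, id = 1L),
                ref_table(0:5, 20, 10, id = 2L))
  ev <- association_runs(tr, refs, radius_px = 3, metadata = md)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$ref_id, c(1L, 2L))
})

test_that("frame bookkeeping is conserved over a track", {
  set.seed(72)
  n <- 40L
  tr <- data.frame(track_id = 1L, frame = 0:(n - 1L),
                   x_px = 10 + cumsum(stats::rnorm(n, 0, 2)),
                   y_px = 10, intensity = 1)
  refs <- ref_table(0:(n - 1L), 10, 10)
  ev <- association_runs(tr, refs, radius_px = 3, max_gap_frames = 2L,
                         metadata = md)
  seq_ref <- endotrack:::sticky_ref_sequence(tr$frame, tr$x_px, tr$y_px,
                                             refs, 3)
  in_event <- sum(ev$end_frame - ev$start_frame + 1L)
  gap_in_event <- sum(ev$n_gap_frames)
  associated <- sum(!is.na(seq_ref))
  expect_equal(in_event - gap_in_event, associated)
  expect_lte(in_event, n)
})

test_that("dwell statistics summarize uncensored events by default", {
  ev <- data.frame(track_id = 1L, ref_id = 1L, start_frame = c(1, 5),
                   end_frame = c(2, 8), n_gap_frames = 0L,
                   dwell_s = c(2, 4), censored = FALSE)
  s <- dwell_stats(ev)
  expect_equal(s$mean_s, 3)
  expect_equal(s$n, 2L)
  ev$censored <- TRUE
  expect_error(dwell_stats(ev), "censored")
  expect_equal(dwell_stats(ev, censoring = "include")$mean_s, 3)
  expect_error(dwell_stats(ev[0, ]), "no association events")
})

test_that("dwells are invariant to frame-interval rescaling in frame units", {
  tr <- data.frame(track_id = 1L, frame = 0:9, x_px = 10, y_px = 10,
                   intensity = 1)
  refs <- ref_table(0:9, 10, 10)
  md_a <- movie_metadata(143, 154, 10, "a")
  md_b <- movie_metadata(143, 475, 10, "a")
  ev_a <- association_runs(tr, refs, 3, metadata = md_a)
  ev_b <- association_runs(tr, refs, 3, metadata = md_b)
  expect_equal(ev_a$dwell_s / 0.154, ev_b$dwell_s / 0.475)
})
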