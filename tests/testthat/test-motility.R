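md_154 <- movie_metadata(143, 154, 600, "vesicle")
md_475 <- movie_metadata(143, 475, 600, "vesicle")

track_from_steps <- function(dx) {
  data.frame(track_id = 1L, frame = 0:length(dx),
             x_px = cumsum(c(10, dx)), y_px = 10, intensity = 100)
}

test_that("step classification is strict at the 3-pixel criterion", {
  tr <- track_from_steps(c(2.9, 3.0, 0))
  lab <- classify_steps(tr)
  expect_equal(lab$label, c("immobile", "motile", "immobile"))
  expect_equal(lab$displacement_px, c(2.9, 3.0, 0))
  expect_error(classify_steps(tr[1, , drop = FALSE]), "at least 2")
})

test_that("classification is monotone in the threshold", {
  set.seed(61)
  tr <- data.frame(track_id = 1L, frame = 0:20,
                   x_px = cumsum(stats::runif(21, 0, 5)),
                   y_px = cumsum(stats::runif(21, 0, 5)), intensity = 1)
  expect_true(all(classify_steps(tr, threshold_px = 1e-12)$label == "motile"))
  expect_true(all(classify_steps(tr, threshold_px = Inf)$label == "immobile"))
  thr <- c(0.5, 2, 4, 8)
  n_imm <- vapply(thr, function(t) sum(classify_steps(tr, t)$label == "immobile"),
                  numeric(1))
  expect_true(all(diff(n_imm) >= 0))
})

test_that("pixel-per-frame speed conversion matches the calibration", {
  expect_equal(round(px_frame_to_speed(143, 154), 2), 0.93)
  expect_equal(px_frame_to_speed(100, 100), 1.0)
  expect_equal(round(px_frame_to_speed(143, 475), 4), 0.3011)
  expect_error(px_frame_to_speed(-1, 100), "positive")
})

test_that("track metrics: stationary track and unit straight line", {
  stat <- data.frame(track_id = 1L, frame = 0:9, x_px = 5, y_px = 5,
                     intensity = 1)
  m <- track_metrics(stat, classify_steps(stat), md_154)
  expect_equal(m$path_length_um, 0)
  expect_equal(m$immobile_fraction, 1)
  expect_true(is.na(m$mean_motile_speed_um_s))  # missing, never 0

  line <- track_from_steps(rep(1, 9))   # exactly 1 px/frame
  lab <- classify_steps(line)
  m2 <- track_metrics(line, lab, md_154)
  expect_true(all(lab$label == "immobile"))     # 1 px < 3 px
  expect_equal(m2$mean_step_speed_um_s, 143 / 154, tolerance = 1e-12)
  expect_equal(m2$n_steps, 9L)
  expect_equal(m2$duration_s, 9 * 0.154)
})

test_that("metrics are invariant to time reversal and translation", {
  set.seed(62)
  tr <- data.frame(track_id = 1L, frame = 0:15,
                   x_px = cumsum(stats::rnorm(16, 1, 1)),
                   y_px = cumsum(stats::rnorm(16, 0, 1)), intensity = 1)
  m <- track_metrics(tr, classify_steps(tr), md_475)
  rev_tr <- tr
  rev_tr$x_px <- rev(tr$x_px); rev_tr$y_px <- rev(tr$y_px)
  m_rev <- track_metrics(rev_tr, classify_steps(rev_tr), md_475)
  expect_equal(m$path_length_um, m_rev$path_length_um)
  expect_equal(m$net_displacement_um, m_rev$net_displacement_um)

  shifted <- tr; shifted$x_px <- tr$x_px + 40; shifted$y_px <- tr$y_px - 13
  m_sh <- track_metrics(shifted, classify_steps(shifted), md_475)
  expect_equal(m$mean_step_speed_um_s, m_sh$mean_step_speed_um_s)
  expect_equal(m$net_displacement_um, m_sh$net_displacement_um)
})

test_that("mismatched labels are rejected", {
  tr <- track_from_steps(c(1, 2, 3))
  lab <- classify_steps(tr)
  expect_error(track_metrics(tr, lab[1:2, ], md_154), "steps")
  tr2 <- tr; tr2$x_px <- tr2$x_px + c(0, 1, 0, 0)
  expect_error(track_metrics(tr2, lab, md_154), "not computed from")
})
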