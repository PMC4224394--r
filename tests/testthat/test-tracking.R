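test_that("forced single link and gating contract", {
  a <- data.frame(x_px = 10, y_px = 10, intensity = 100)
  b <- data.frame(x_px = 12, y_px = 10, intensity = 100)
  links <- link_frames(a, b, link_params(gate_radius_px = 5))
  expect_equal(nrow(links), 1L)
  expect_equal(links$i, 1L)
  expect_equal(links$j, 1L)

  far <- data.frame(x_px = 17, y_px = 10, intensity = 100)
  expect_equal(nrow(link_frames(a, far, link_params(gate_radius_px = 5))), 0L)
  expect_equal(nrow(link_frames(a[0, ], b)), 0L)
})

test_that("intensity disambiguates crossing detections", {
  # two detections swap positions; intensities are preserved, so with
  # w_int > 0 the optimal assignment follows intensity identity
  t0 <- data.frame(x_px = c(10, 12), y_px = c(10, 10), intensity = c(100, 200))
  t1 <- data.frame(x_px = c(12, 10), y_px = c(10, 10), intensity = c(100, 200))
  p <- link_params(gate_radius_px = 5, w_dist = 1, w_int = 0.5,
                   intensity_scale = 100)
  links <- link_frames(t0, t1, p)
  links <- links[order(links$i), ]
  # by-hand enumeration: identity-preserving assignment costs
  # 2*(1*(2/5)) = 0.8; proximity-preserving costs 0 + 2*(0.5*100/100) = 1.0
  expect_equal(links$j, c(1L, 2L))
})

test_that("assignment cost equals brute-force enumeration on random instances", {
  set.seed(51)
  p <- link_params(gate_radius_px = 6, w_dist = 1, w_int = 0.5,
                   intensity_scale = 100)
  for (r in 1:150) {
    a <- random_detection_frame(sample(0:5, 1))
    b <- random_detection_frame(sample(0:5, 1))
    links <- link_frames(a, b, p)
    got <- realized_link_cost(links, a, b, 6, 1, 0.5, 100, p$cost_unmatched)
    want <- brute_force_link_cost(a, b, 6, 1, 0.5, 100, p$cost_unmatched)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("track assembly: stationary chain, no gap closing, conservation", {
  det <- data.frame(frame = 0:9, x_px = 10, y_px = 10, intensity = 100)
  tr <- build_tracks(det)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 10L)

  det2 <- det[det$frame != 5L, ]
  tr2 <- build_tracks(det2)
  expect_equal(length(unique(tr2$track_id)), 2L)
  lens <- as.integer(table(tr2$track_id))
  expect_equal(sort(lens), c(4L, 5L))
  for (id in unique(tr2$track_id)) {
    fr <- tr2$frame[tr2$track_id == id]
    expect_true(all(diff(fr) == 1L))   # strictly consecutive frames
  }

  # conservation: tracked detections + singletons = input detections
  set.seed(52)
  det3 <- do.call(rbind, lapply(0:5, function(f)
    cbind(frame = f, random_detection_frame(sample(1:4, 1)))))
  tr3 <- build_tracks(det3, link_params(gate_radius_px = 4))
  expect_equal(nrow(tr3) + attr(tr3, "n_singletons"), nrow(det3))
})

test_that("detection input order does not change the track set", {
  set.seed(53)
  det <- do.call(rbind, lapply(0:7, function(f)
    data.frame(frame = f, x_px = c(5, 20, 40) + stats::rnorm(3, 0, 0.3),
               y_px = c(5, 20, 40) + stats::rnorm(3, 0, 0.3),
               intensity = c(90, 110, 130))))
  tr1 <- build_tracks(det)
  tr2 <- build_tracks(det[sample.int(nrow(det)), ])
  key <- function(tr) {
    tr <- tr[order(tr$track_id, tr$frame), ]
    unname(split(paste(tr$frame, round(tr$x_px, 6), round(tr$y_px, 6)),
                 tr$track_id))
  }
  expect_setequal(key(tr1), key(tr2))
})

test_that("track-length filter implements the strict more-than-5-frames rule", {
  mk <- function(id, n) data.frame(track_id = id, frame = seq_len(n) - 1L,
                                   x_px = 0, y_px = 0, intensity = 1)
  tracks <- rbind(mk(1L, 5L), mk(2L, 6L))
  kept <- filter_tracks(tracks, min_frames = 6L)
  expect_equal(unique(kept$track_id), 2L)   # 5-frame track removed
  expect_equal(nrow(kept), 6L)              # 6-frame track retained
  expect_equal(nrow(filter_tracks(tracks[0, ])), 0L)
  expect_error(filter_tracks(tracks, min_frames = 1L), "min_frames")
})

test_that("unordered or fractional frames are rejected", {
  det <- data.frame(frame = c(0, 1.5), x_px = 1, y_px = 1, intensity = 1)
  expect_error(build_tracks(det), "integer")
})
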