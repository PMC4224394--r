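test_that("bleach correction: identity, analytic decay, error contract", {
  arr <- array(rep(matrix(5, 8, 8), 10), dim = c(8, 8, 10))
  expect_equal(bleach_correct(arr), arr)

  template <- matrix(stats::runif(16 * 16, 1, 10), 16, 16)
  dec <- array(0, dim = c(16, 16, 25))
  for (k in 1:25) dec[, , k] <- template * exp(-(k - 1) / 100)
  out <- bleach_correct(dec, "first_frame")
  means <- apply(out, 3, mean)
  expect_true(all(abs(means / means[1] - 1) < 1e-6))

  bad <- dec
  bad[, , 7] <- 0
  expect_error(bleach_correct(bad), "frame 6")
})

test_that("global-median reference normalizes to the median level", {
  arr <- array(0, dim = c(8, 8, 5))
  for (k in 1:5) arr[, , k] <- k
  out <- bleach_correct(arr, "global_median")
  expect_equal(apply(out, 3, mean), rep(3, 5))
})

test_that("a-trous decomposition is additive and kills constants", {
  set.seed(31)
  for (rep in 1:5) {
    img <- matrix(stats::rnorm(48 * 40), 48, 40)
    dec <- atrous_decompose(img, 3)
    rec <- Reduce(`+`, dec$details) + dec$residual
    expect_lt(max(abs(rec - img)), 1e-9)
  }
  const <- matrix(7, 32, 32)
  dec <- atrous_decompose(const, 3)
  for (d in dec$details) expect_lt(max(abs(d)), 1e-12)
})

test_that("impulse response matches the separable B3 kernel by hand", {
  img <- matrix(0, 33, 33)
  img[17, 17] <- 1
  dec <- atrous_decompose(img, 2)
  # central smoothing weight of the 2-D separable (1,4,6,4,1)/16 kernel is
  # (6/16)^2; the first detail plane keeps the rest
  expect_equal(dec$details[[1]][17, 17], 1 - (6 / 16)^2)
})

test_that("too many scales for the image size is an error", {
  expect_error(atrous_decompose(matrix(0, 16, 16), 4), "n_scales")
})

test_that("spot detection: empty image, sub-pixel accuracy, separation", {
  expect_equal(nrow(detect_spots(matrix(0, 64, 64))), 0L)

  f <- spot_frame(64, 64, data.frame(x = 20.3, y = 30.7),
                  sigma = 1.5, amplitude = 50, noise_sd = 1, seed = 32)
  d <- detect_spots(f)
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$x_px - 20.3), 0.5)
  expect_lt(abs(d$y_px - 30.7), 0.5)

  f2 <- spot_frame(64, 64, data.frame(x = c(20.3, 30.3), y = c(30.7, 30.7)),
                   sigma = 1.5, amplitude = 50, noise_sd = 1, seed = 33)
  d2 <- detect_spots(f2)
  expect_equal(nrow(d2), 2L)
})

test_that("watershed splitting resolves touching spots", {
  f <- spot_frame(64, 64, data.frame(x = c(28, 32), y = c(30, 30)),
                  sigma = 1.3, amplitude = 60, noise_sd = 1, seed = 34)
  merged <- detect_spots(f, split_touching = FALSE)
  split <- detect_spots(f, split_touching = TRUE)
  expect_equal(nrow(merged), 1L)
  expect_equal(nrow(split), 2L)
})

test_that("detection is translation-equivariant for integer shifts", {
  f <- spot_frame(64, 64, data.frame(x = 25.4, y = 33.2),
                  sigma = 1.5, amplitude = 40, noise_sd = 0)
  shifted <- matrix(0, 64, 64)
  shifted[6:64, ] <- f[1:59, ]   # shift down 5 rows (y += 5)
  a <- detect_spots(f)
  b <- detect_spots(shifted)
  expect_equal(nrow(a), 1L)
  expect_equal(nrow(b), 1L)
  expect_equal(b$y_px - a$y_px, 5, tolerance = 1e-6)
  expect_equal(b$x_px - a$x_px, 0, tolerance = 1e-6)
})

test_that("detect_movie assembles per-frame tables with 0-based frames", {
  arr <- array(0, dim = c(64, 64, 3))
  for (k in 1:3)
    arr[, , k] <- spot_frame(64, 64, data.frame(x = 20 + k, y = 30),
                             sigma = 1.5, amplitude = 50, noise_sd = 1,
                             seed = 40 + k) + 10
  det <- detect_movie(arr, correct_bleach = FALSE)
  expect_equal(sort(unique(det$frame)), 0:2)
  expect_equal(nrow(det), 3L)
})
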