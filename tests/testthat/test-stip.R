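test_that("a temporally constant volume has no interest points", {
  v <- array(rep(mkSmoothTexture(32, seed = 4), 10), c(32, 32, 10))
  expect_identical(nrow(harris3d(v)), 0L)
})

test_that("the corner response is invariant to a constant intensity offset", {
  set.seed(8)
  v <- array(runif(24 * 24 * 8), c(24, 24, 8))
  h1 <- ActiveTracker:::harris3dResponse(v)
  h2 <- ActiveTracker:::harris3dResponse(v + 0.3)
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("an abrupt appearance event produces a nearby interest point", {
  set.seed(12)
  v <- array(0.15, c(32, 32, 12))
  patch <- 0.55 + 0.4 * mkSmoothTexture(8, seed = 5, sigma = 1)
  for (t in 7:12) v[13:20, 13:20, t] <- patch     # onset at t = 6 (0-based)
  s <- harris3d(v)
  expect_gt(nrow(s), 0L)
  near <- sqrt((s$x - 16)^2 + (s$y - 16)^2) <= 5 & abs(s$t - 6) <= 2
  expect_true(any(near))
})

test_that("reported responses match a dense direct-convolution oracle", {
  for (i in 1:3) {
    v <- eventVolume(onset = 1L + i, seed = 20 + i)
    Ho <- denseHarrisOracle(v)
    s <- harris3d(v, threshold = 1e-12)
    expect_gt(nrow(s), 0L)
    for (j in seq_len(nrow(s))) {
      expect_equal(s$response[j], Ho[s$y[j] + 1, s$x[j] + 1, s$t[j] + 1],
                   tolerance = 1e-9)
      # a strict local maximum of the oracle volume too
      nb <- Ho[s$y[j] + 0:2, s$x[j] + 0:2, s$t[j] + 0:2]
      expect_equal(max(nb), s$response[j])
    }
  }
})

test_that("interest-point density is count over area with frame rounding", {
  pts <- data.frame(x = c(1, 5, 10, 30), y = c(1, 5, 10, 5),
                    t = c(0, 0, 0.4, 0), response = 1)
  box <- bbox(0, 0, 20, 25)
  expect_equal(activitySTIP(box, pts, frame = 0), 3 / 500)
  expect_equal(activitySTIP(box, pts[0, ], frame = 0), 0)
  # doubling the area with the same contained points halves the density
  expect_equal(activitySTIP(bbox(0, 0, 40, 25), pts, frame = 0),
               activitySTIP(box, pts, frame = 0) * (3 + 1) / (2 * 3))
  # t = 0.6 rounds to frame 1, not 0
  pts2 <- data.frame(x = 5, y = 5, t = 0.6, response = 1)
  expect_equal(activitySTIP(box, pts2, frame = 0), 0)
  expect_equal(activitySTIP(box, pts2, frame = 1), 1 / 500)
})

test_that("too-short volumes are rejected", {
  expect_error(harris3d(array(0, c(8, 8, 2))), "at least 3 frames")
})
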