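gtFrame <- function(frame, x, y = 0, w = 10, h = 10)
  data.frame(frame = frame, x = x, y = y, w = w, h = h)

test_that("detection evaluation matches greedily at the IoU threshold", {
  gt <- rbind(gtFrame(0, 0), gtFrame(0, 50), gtFrame(1, 20))
  perfect <- evalDetections(gt, gt)
  expect_identical(c(perfect@tp, perfect@fp, perfect@fn), c(3L, 0L, 0L))
  expect_equal(perfect@precision, 1)
  expect_equal(perfect@recall, 1)

  # one prediction at IoU 0.4 < 0.5: both a false positive and a miss
  pred <- gtFrame(0, 0 + 10 * (1 - 0.4) / (1 + 0.4))  # IoU = 0.4 overlap
  pred$x <- 4.286
  r <- evalDetections(pred, gtFrame(0, 0))
  expect_identical(c(r@tp, r@fp, r@fn), c(0L, 1L, 1L))

  none <- evalDetections(gtFrame(0, 0)[0, ], gtFrame(0, 0))
  expect_identical(none@recall, 0)
  expect_true("no-predictions" %in% none@note)
  expect_identical(none@precision, 0)
})

test_that("frame-level activity uses the largest-IoU rule with min overlap", {
  gtA <- gtFrame(0, 0)
  dets <- rbind(gtFrame(0, 0), gtFrame(0, 40))
  exact <- evalFrameActivity(gtFrame(0, 0), gtA, dets)
  expect_identical(c(exact@tp, exact@fp, exact@fn), c(1L, 0L, 0L))

  # overlap below the 10% minimum is not a true positive
  low <- gtFrame(0, 9.1)        # IoU just over 0.047
  expect_lt(boxIoU(c(x = 9.1, y = 0, w = 10, h = 10),
                   c(x = 0, y = 0, w = 10, h = 10)), 0.1)
  r <- evalFrameActivity(low, gtA, rbind(low, gtFrame(0, 40)))
  expect_identical(c(r@tp, r@fn), c(0L, 1L))

  # another detection overlaps the ground truth more: not a true positive
  better <- gtFrame(0, 2)       # IoU ~ 0.67 with gt
  chosen <- gtFrame(0, 5)       # IoU ~ 0.33, still above the minimum
  r2 <- evalFrameActivity(chosen, gtA, rbind(better, chosen))
  expect_identical(c(r2@tp, r2@fn), c(0L, 1L))

  # prediction in a frame with no ground truth is a false positive;
  # a tie-suppressed (absent) prediction where ground truth exists is a miss
  r3 <- evalFrameActivity(gtFrame(1, 0), gtA, gtFrame(1, 0))
  expect_identical(c(r3@tp, r3@fp, r3@fn), c(0L, 1L, 1L))

  expect_error(evalFrameActivity(rbind(gtFrame(0, 0), gtFrame(0, 3)),
                                 gtA, dets), "more than one")
})

test_that("track-level decision thresholds the matching-frame fraction", {
  gt <- gtFrame(0:9, x = 0)
  allGood <- evalTrack(gt, gt)
  expect_identical(allGood, 1L)

  # 6 of 10 frames overlapping at IoU >= 0.5 -> fraction 0.6 >= 0.5
  tr <- gt
  tr$x[7:10] <- 50
  expect_identical(evalTrack(tr, gt, alpha = 0.5, theta = 0.5), 1L)
  # 4 of 10 -> 0.4 < 0.5
  tr$x[5:10] <- 50
  expect_identical(evalTrack(tr, gt, alpha = 0.5, theta = 0.5), 0L)
  # exactly theta passes (the comparison is inclusive)
  tr2 <- gt
  tr2$x[6:10] <- 50
  expect_identical(evalTrack(tr2, gt, alpha = 0.5, theta = 0.5), 1L)
  # frames absent from the ground truth count as non-matching
  expect_identical(evalTrack(gtFrame(0:9, 0), gtFrame(0:4, 0),
                             theta = 0.5), 1L)
  expect_identical(evalTrack(gtFrame(0:9, 0), gtFrame(0:3, 0),
                             theta = 0.5), 0L)
  expect_error(evalTrack(gt[0, ], gt), "empty")
})

test_that("TPR% is the mean in percent and is monotone", {
  expect_equal(tprPercent(c(1, 1, 1)), 100)
  expect_equal(tprPercent(c(1, 0, 1, 0)), 50)
  set.seed(41)
  res <- sample(0:1, 20, replace = TRUE)
  for (i in which(res == 0)) {
    flipped <- res
    flipped[i] <- 1
    expect_gte(tprPercent(flipped), tprPercent(res))
  }
  expect_error(tprPercent(integer()), "no track results")
})

test_that("TPR% is non-increasing in alpha and theta", {
  set.seed(42)
  # a fixed synthetic result set: tracks with varying overlap quality
  tracks <- lapply(1:8, function(i) {
    gt <- gtFrame(0:19, x = 0)
    tr <- gt
    off <- sample(0:19, sample(0:19, 1))
    tr$x[off + 1] <- runif(length(off), 2, 12)   # degrade some frames
    list(tr = tr, gt = gt)
  })
  tprAt <- function(alpha, theta)
    tprPercent(vapply(tracks, function(p)
      evalTrack(p$tr, p$gt, alpha = alpha, theta = theta), integer(1)))
  alphas <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  byAlpha <- vapply(alphas, tprAt, numeric(1), theta = 0.5)
  expect_true(all(diff(byAlpha) <= 0))
  byTheta <- vapply(alphas, function(th) tprAt(0.5, th), numeric(1))
  expect_true(all(diff(byTheta) <= 0))
  # degenerate limits: any overlapping track passes as alpha, theta -> 0
  expect_identical(evalTrack(tracks[[1]]$tr, tracks[[1]]$gt,
                             alpha = 1e-9, theta = 1e-9), 1L)
})
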