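test_that("frame ranking uses competition ranks and flags a unique top", {
  one <- rankFrame(data.frame(frame = 0L, track_id = 4L, value = 2))
  expect_identical(one$ranks, c(`4` = 1L))
  expect_identical(one$active, 4L)

  r <- rankFrame(data.frame(track_id = c(6, 1, 2), value = c(0.9, 0.5, 0.3)))
  expect_identical(r$ranks, c(`6` = 1L, `1` = 2L, `2` = 3L))
  expect_identical(r$active, 6L)

  tie <- rankFrame(data.frame(track_id = c(1, 2, 3), value = c(5, 5, 1)))
  expect_identical(tie$active, NA_integer_)
  expect_identical(unname(tie$ranks), c(1L, 1L, 3L))
  expect_identical(tie$winners, c(1L, 2L))

  expect_error(rankFrame(data.frame(track_id = c(1, 1), value = 1:2)),
               "duplicate")
})

test_that("a frame with no measured activity contributes no winner", {
  r <- rankFrame(data.frame(track_id = 1:3, value = c(0, 0, 0)))
  expect_identical(r$winners, integer(0))
  expect_identical(r$active, NA_integer_)
})

test_that("the worked five-frame example reproduces its wins and winner", {
  sv <- accumulateRankings(table1Rankings())
  expect_identical(sv$wins, c(`1` = 1L, `2` = 0L, `6` = 5L, `9` = 0L))
  sel <- selectActive(sv)
  expect_identical(activeTrack(sel), 6L)
  expect_identical(unname(which.max(wins(sel))),
                   match("6", names(wins(sel))))
  # the tied fourth frame has no active flag
  expect_identical(sv$frameActive$active, c(6L, 6L, 6L, NA, 6L))
  # undetected frames leave gaps in the score vectors
  expect_identical(sv$ranks$frame[sv$ranks$id == 9L], c(3L, 4L))
})

test_that("accumulation handles empty input and counts straight wins", {
  empty <- accumulateRankings(list())
  expect_identical(nrow(empty$ranks), 0L)
  expect_identical(length(empty$wins), 0L)

  rks <- lapply(0:4, function(f)
    rankFrame(data.frame(frame = f, track_id = c(1, 2),
                         value = c(2, 1))))
  sv <- accumulateRankings(rks)
  expect_identical(sv$wins, c(`1` = 5L, `2` = 0L))

  expect_error(accumulateRankings(rks[c(2, 1)]), "strictly increasing")
})

test_that("selection ties break by track length then lower id", {
  mk <- function(f, ids, vals)
    rankFrame(data.frame(frame = f, track_id = ids, value = vals))
  # a wins frames 0-2, b wins frames 3-5, but a is tracked longer
  rks <- list(mk(0, c(1, 2), c(2, 1)), mk(1, c(1, 2), c(2, 1)),
              mk(2, c(1, 2), c(2, 1)), mk(3, c(1, 2), c(1, 2)),
              mk(4, c(1, 2), c(1, 2)), mk(5, c(1, 2), c(1, 2)),
              mk(6, c(1), c(0)))    # zero activity: no win, but 1 is longer
  sv <- accumulateRankings(rks)
  expect_identical(sv$wins[["1"]], sv$wins[["2"]])
  expect_identical(activeTrack(selectActive(sv)), 1L)

  # equal wins and equal lengths -> lower id
  sv2 <- accumulateRankings(rks[1:6])
  expect_identical(activeTrack(selectActive(sv2)), 1L)

  # nobody ever wins -> no active track
  sv3 <- accumulateRankings(list(mk(0, 1:2, c(0, 0))))
  sel3 <- selectActive(sv3)
  expect_identical(activeTrack(sel3), NA_integer_)
})

test_that("selection is invariant under monotone transforms of activity", {
  set.seed(31)
  act <- do.call(rbind, lapply(0:19, function(f)
    data.frame(frame = f, track_id = 1:4, measure = "of",
               value = runif(4, 0.01, 3))))
  s1 <- selectActive(rankActivity(act)$scoreVectors)
  act2 <- act
  act2$value <- exp(5 * act$value) - 1       # strictly monotone, keeps 0
  s2 <- selectActive(rankActivity(act2)$scoreVectors)
  expect_identical(activeTrack(s1), activeTrack(s2))
  expect_identical(wins(s1), wins(s2))
})

test_that("each frame has at most one active flag", {
  set.seed(32)
  act <- do.call(rbind, lapply(0:9, function(f)
    data.frame(frame = f, track_id = 1:3, measure = "of",
               value = sample(c(1, 1, 2)))))
  out <- rankActivity(act)
  perFrame <- tapply(out$activity$is_active, out$activity$frame, sum)
  expect_true(all(perFrame <= 1))
})
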