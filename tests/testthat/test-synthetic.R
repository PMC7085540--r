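test_that("scene generation is deterministic and respects the frame", {
  cfg <- smallSceneConfig(seed = 5)
  s1 <- generateScene(cfg)
  s2 <- generateScene(cfg)
  expect_identical(s1$frames, s2$frames)
  expect_identical(truthBoxes(s1$truth), truthBoxes(s2$truth))
  b <- truthBoxes(s1$truth)
  expect_true(all(b$x >= 0 & b$y >= 0 &
                  b$x + b$w <= 120 & b$y + b$h <= 96))
  expect_identical(nrow(b), 30L * 3L)            # one box per sprite per frame
  expect_true(all(s1$frames[[1]] >= 0 & s1$frames[[1]] <= 1))
})

test_that("zero-speed sprites and zero noise give identical frames", {
  sprites <- list(
    spriteSpec(1, x0 = 10, y0 = 10, xmin = 0, xmax = 60, speed = 0),
    spriteSpec(2, x0 = 40, y0 = 50, xmin = 0, xmax = 60, speed = 0,
               active = TRUE))
  cfg <- sceneConfig(frameWidth = 80, frameHeight = 80, nFrames = 5,
                     sprites = sprites, noiseSd = 0)
  sc <- generateScene(cfg)
  for (f in 2:5) expect_identical(sc$frames[[f]], sc$frames[[1]])
})

test_that("ground-truth displacement equals the configured speed", {
  sprites <- list(
    spriteSpec(1, x0 = 0, y0 = 10, xmin = 0, xmax = 100, speed = 2),
    spriteSpec(2, x0 = 0, y0 = 40, xmin = 0, xmax = 100, speed = 3,
               active = TRUE))
  cfg <- sceneConfig(frameWidth = 130, frameHeight = 80, nFrames = 20,
                     sprites = sprites, noiseSd = 0)
  b <- truthBoxes(generateScene(cfg)$truth)
  for (id in 1:2) {
    x <- b$x[b$id == id]
    expect_true(all(abs(diff(x)) == cfg$sprites[[id]]$speed))
  }
})

test_that("the active sprite out-travels the others at the default factor", {
  for (seed in 1:5) {
    cfg <- sceneConfig(seed = seed)
    sc <- generateScene(cfg)
    b <- truthBoxes(sc$truth)
    disp <- vapply(split(b, b$id), function(d)
      mean(abs(diff(d$x))), numeric(1))
    act <- as.character(activeId(sc$truth))
    expect_equal(unname(disp[act]), 3)
    expect_true(all(disp[setdiff(names(disp), act)] <= 1))
    expect_gte(disp[[act]], 3 * max(disp[setdiff(names(disp), act)]))
  }
})

test_that("unperturbed detections reproduce the truth exactly", {
  sc <- generateScene(smallSceneConfig(seed = 3))
  d <- detections(perturbDetections(sc$truth, jitterSd = 0, dropoutP = 0,
                                    fpRate = 0, seed = 2))
  b <- truthBoxes(sc$truth)
  expect_identical(nrow(d), nrow(b))
  od <- d[order(d$frame, d$x, d$y), c("x", "y", "w", "h")]
  ob <- b[order(b$frame, b$x, b$y), c("x", "y", "w", "h")]
  expect_equal(od, ob, ignore_attr = TRUE)
  # deterministic given the seed
  d2 <- detections(perturbDetections(sc$truth, jitterSd = 0, dropoutP = 0,
                                     fpRate = 0, seed = 2))
  expect_identical(d, d2)
})

test_that("full dropout leaves only false positives", {
  sc <- generateScene(smallSceneConfig(seed = 3))
  d <- detections(perturbDetections(sc$truth, dropoutP = 1, fpRate = 2,
                                    seed = 7))
  expect_gt(nrow(d), 0L)
  b <- truthBoxes(sc$truth)
  key <- paste(b$frame, round(b$x, 6), round(b$y, 6))
  expect_false(any(paste(d$frame, round(d$x, 6), round(d$y, 6)) %in% key))
})

test_that("dropout keeps a binomially plausible number of boxes", {
  cfg <- sceneConfig(nFrames = 200L, seed = 13)      # 5 x 200 = 1000 boxes
  truth <- generateScene(cfg)$truth
  expect_identical(nrow(truthBoxes(truth)), 1000L)
  kept <- nrow(detections(perturbDetections(truth, dropoutP = 0.2,
                                            fpRate = 0, seed = 99)))
  expect_lt(abs(kept - 800), 3 * sqrt(1000 * 0.2 * 0.8))
})

test_that("the oracle scorer returns IoU with the active ground truth", {
  sc <- generateScene(smallSceneConfig(seed = 6))
  scorer <- oracleScorer(sc$truth)
  b <- truthBoxes(sc$truth)
  act <- b[b$id == activeId(sc$truth) & b$frame == 4, ]
  box <- bbox(act$x, act$y, act$w, act$h)
  expect_equal(scorer(4L, box), 1)
  expect_equal(scorer(4L, bbox(act$x + 200, act$y, act$w, act$h)), 0)
  half <- bbox(act$x + act$w / 2, act$y, act$w, act$h)
  expect_equal(scorer(4L, half), 1 / 3)
})

test_that("invalid scenes are rejected at configuration time", {
  sprites <- list(spriteSpec(1, x0 = 90, y0 = 10, xmin = 0, xmax = 200,
                             speed = 5, active = TRUE))
  expect_error(sceneConfig(frameWidth = 100, frameHeight = 50,
                           nFrames = 30, sprites = sprites),
               "leaves the frame")
  expect_error(sceneConfig(sprites = list(spriteSpec(1))),
               "exactly one sprite")
})
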