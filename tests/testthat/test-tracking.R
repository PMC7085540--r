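mkTrack <- function(box, id = 1L) {
  list(id = id, frames = 0L, boxes = asBoxMatrix(box), misses = 0L,
       closed = FALSE)
}

test_that("the Hungarian cost blends centroid distance and area difference", {
  a <- bbox(5, 5, 10, 10)        # centred (10, 10), area 100
  b <- bbox(7.5, 9, 11, 10)      # centred (13, 14), area 110
  expect_equal(hungarianCost(mkTrack(a), b, w = 0.5, T = 100), 7.5)
  expect_equal(hungarianCost(mkTrack(a), a), 0)
  far <- bbox(125, 5, 10, 10)    # 120 px away
  expect_identical(hungarianCost(mkTrack(a), far, T = 100), Inf)
  # the gate is strict: d == T is already infeasible
  atT <- bbox(105, 5, 10, 10)
  expect_identical(hungarianCost(mkTrack(a), atT, T = 100), Inf)
  expect_error(hungarianCost(list(id = 1L, boxes = asBoxMatrix(a)[0, , drop = FALSE]), a),
               "no assignments")
})

test_that("frame assignment is globally optimal and reports leftovers", {
  cfg <- pipelineConfig(w = 1)
  dets <- data.frame(x = c(0, 8), y = 0, w = 2, h = 2)
  res <- assignHungarian(list(), dets, cfg)
  expect_identical(nrow(res$matches), 0L)
  expect_identical(res$unmatchedDetections, 1:2)

  tracks <- list(mkTrack(bbox(-1, -1, 2, 2), 1L),   # centred (0, 0)
                 mkTrack(bbox(9, -1, 2, 2), 2L))    # centred (10, 0)
  dets <- data.frame(x = c(0, 8), y = -1, w = 2, h = 2)  # centred 1, 9
  res <- assignHungarian(tracks, dets, cfg)
  # nearest-neighbour total cost 2 beats the crossed assignment's 18
  expect_equal(res$matches[, "detection"][order(res$matches[, "track"])],
               c(1L, 2L))
})

test_that("the assignment solver equals the exhaustive oracle", {
  set.seed(23)
  for (i in 1:80) {
    nr <- sample(0:6, 1)
    nc <- sample(0:6, 1)
    cost <- matrix(round(runif(nr * nc, 0, 50), 2), nr, nc)
    if (length(cost) > 0L) cost[runif(nr * nc) < 0.25] <- Inf
    sol <- solveAssignment(cost)
    bf <- bruteForceAssignment(cost)
    expect_identical(nrow(sol$matches), bf$k)
    expect_equal(sol$cost, bf$cost, tolerance = 1e-9)
  }
})

test_that("track lifecycle: misses, closure after M, resume within M", {
  cfg <- pipelineConfig(M = 20L)
  box <- data.frame(x = 10, y = 10, w = 8, h = 12)
  st <- stepTracker(newTracker(), 0L, box, cfg)
  expect_identical(length(st$tracks), 1L)
  # unmatched for 21 consecutive steps -> closed; 20 would still be open
  empty <- box[0, ]
  for (f in 1:20) st <- stepTracker(st, f, empty, cfg)
  expect_false(st$tracks[[1]]$closed)
  st <- stepTracker(st, 21L, empty, cfg)
  expect_true(st$tracks[[1]]$closed)

  # a detection re-appearing after a 5-frame gap resumes the same id
  st2 <- stepTracker(newTracker(), 0L, box, cfg)
  for (f in 1:5) st2 <- stepTracker(st2, f, empty, cfg)
  st2 <- stepTracker(st2, 6L, data.frame(x = 12, y = 10, w = 8, h = 12), cfg)
  expect_identical(length(st2$tracks), 1L)
  expect_identical(st2$tracks[[1]]$frames, c(0L, 6L))
  expect_identical(st2$tracks[[1]]$misses, 0L)

  # every detection matched -> no new tracks
  st3 <- stepTracker(newTracker(), 0L,
                     data.frame(x = c(0, 50), y = 0, w = 8, h = 8), cfg)
  st3 <- stepTracker(st3, 1L, data.frame(x = c(1, 51), y = 0, w = 8, h = 8), cfg)
  expect_identical(length(st3$tracks), 2L)

  # frames must advance strictly
  expect_error(stepTracker(st3, 1L, empty, cfg), "not after")
})

test_that("Mahalanobis distance is a quadratic form with its invariances", {
  mu <- c(10, 20, 0.5, 30)
  S <- diag(4)
  expect_equal(mahalanobisDistance(mu, S, mu), 0)
  expect_equal(mahalanobisDistance(c(0, 0, 0, 0), 4 * diag(4),
                                   c(2, 0, 0, 0)), 1)
  z <- c(11, 21, 0.6, 31)
  d1 <- mahalanobisDistance(mu, S, z)
  expect_equal(mahalanobisDistance(mu, 5 * S, z), d1 / 5)
  expect_error(mahalanobisDistance(mu, matrix(0, 4, 4), z),
               "positive-definite")
})

test_that("appearance distance is the min cosine distance to the gallery", {
  r <- c(1, 0)
  expect_equal(appearanceDistance(list(c(0, 1), r), r), 0)
  expect_equal(appearanceDistance(list(c(0, 1)), r), 1)
  g <- list(c(1, 0), c(0.6, 0.8))
  expect_equal(appearanceDistance(g, c(0.8, 0.6)), 0.04)
  expect_error(appearanceDistance(list(), r), "empty")
})

test_that("the blended cost honours lambda and both gates", {
  expect_equal(deepsortCost(2, 0.04, lambda = 1), 2)
  expect_equal(deepsortCost(2, 0.04, lambda = 0), 0.04)
  expect_equal(deepsortCost(2, 0.04, lambda = 0.5), 1.02)
  expect_identical(deepsortCost(9.5, 0.04), Inf)    # Mahalanobis gate
  expect_identical(deepsortCost(2, 0.25), Inf)      # appearance gate
})

test_that("the histogram embedder is deterministic, unit-norm, discriminative", {
  set.seed(3)
  frame <- matrix(runif(60 * 80), 60, 80)
  b <- bbox(10, 10, 20, 20)
  d1 <- defaultEmbedder(frame, b)
  expect_identical(length(d1), 128L)
  expect_equal(sqrt(sum(d1^2)), 1)
  expect_identical(d1, defaultEmbedder(frame, b))
  expect_equal(appearanceDistance(list(d1), d1), 0)
  for (i in 1:100) {
    bb <- bbox(runif(1, 0, 60), runif(1, 0, 40), runif(1, 3, 20),
               runif(1, 3, 20))
    expect_equal(sqrt(sum(defaultEmbedder(frame, bb)^2)), 1)
  }
  # disjoint solid intensities occupy disjoint histogram bins
  dark <- matrix(0.1, 40, 40)
  light <- matrix(0.9, 40, 40)
  expect_gt(appearanceDistance(list(defaultEmbedder(dark, b)),
                               defaultEmbedder(light, b)), 0.99)
  expect_error(defaultEmbedder(frame, bbox(200, 200, 5, 5)), "outside")
})

test_that("gallery is bounded with oldest-first eviction", {
  cfg <- pipelineConfig(tracker = "deepsort", gallerySize = 5L,
                        gateAppearance = 1, gateMahalanobis = 100)
  frames <- lapply(1:8, function(i) matrix(i / 10, 30, 30))
  st <- newTracker()
  for (f in 0:7)
    st <- stepTracker(st, f, data.frame(x = 5, y = 5, w = 10, h = 10), cfg,
                      image = frames[[f + 1]])
  expect_identical(length(st$tracks), 1L)
  g <- st$tracks[[1]]$gallery
  expect_identical(length(g), 5L)
  # the oldest retained descriptor is that of frame 3 (intensity 0.4)
  expect_identical(g[[1]], defaultEmbedder(frames[[4]], bbox(5, 5, 10, 10)))
})

test_that("ids are unique, never reused, and one-to-one per frame", {
  set.seed(5)
  cfg <- pipelineConfig()
  st <- newTracker()
  for (f in 0:14) {
    n <- sample(0:4, 1)
    dets <- if (n > 0)
      data.frame(x = runif(n, 0, 140), y = runif(n, 0, 100),
                 w = runif(n, 5, 15), h = runif(n, 5, 15))
    else data.frame(x = numeric(), y = numeric(), w = numeric(),
                    h = numeric())
    st <- stepTracker(st, f, dets, cfg)
    ids <- vapply(st$tracks, `[[`, integer(1), "id")
    expect_identical(anyDuplicated(ids), 0L)
    lastAt <- unlist(lapply(st$tracks, function(t) t$frames[t$frames == f]))
    expect_lte(length(lastAt), max(n, 0))   # one assignment per detection
  }
  expect_identical(st$nextId - 1L, max(vapply(st$tracks, `[[`, integer(1),
                                              "id")))
})

test_that("clean detection streams give one track per sprite, no switches", {
  sc <- generateScene(smallSceneConfig(seed = 2))
  dets <- perturbDetections(sc$truth, jitterSd = 0, dropoutP = 0,
                            fpRate = 0, seed = 1)
  for (tracker in c("hungarian", "deepsort")) {
    cfg <- pipelineConfig(tracker = tracker)
    ts <- trackDetections(dets, cfg, frames = sc$frames)
    expect_identical(length(trackIds(ts)), 3L)
    # every track follows exactly one sprite at IoU 1 throughout
    tb <- truthBoxes(sc$truth)
    for (id in trackIds(ts)) {
      bx <- trackBoxes(ts, id)
      expect_identical(nrow(bx), nFrames(sc$truth))
      first <- tb[tb$frame == 0 & tb$x == bx$x[1] & tb$y == bx$y[1], ]
      expect_identical(nrow(first), 1L)
      gt <- tb[tb$id == first$id, ]
      expect_true(all(abs(bx$x - gt$x) < 1e-9))
    }
  }
})

test_that("appearance re-identifies through an occlusion the distance gate finds ambiguous", {
  # Bright subject A rests at x = 10 (centre 14) and is occluded for 7
  # frames while dark subject B approaches from the right, last seen
  # centred at x = 26. At frame 15 two detections appear, both centred on
  # the perpendicular bisector (x-centre 20) of the two tracks' last
  # centroids: a bright box in A's lane and a dark box one lane below.
  # Both pairings then have identical total centroid-distance cost, so the
  # spatial cost alone cannot identify A; appearance must resolve it.
  w <- 8; h <- 16
  mkFrame <- function(boxes) {
    f <- matrix(0.5, 52, 64)
    for (b in boxes) f[b$y + 1:h, b$x + 1:w] <- b$v
    f
  }
  xB <- function(f) 36 - f       # B moves left 1 px/frame
  frames <- list(); detRows <- list()
  for (f in 0:15) {
    boxes <- list()
    rows <- NULL
    if (f <= 7) {                                  # A visible, at rest
      boxes <- c(boxes, list(list(x = 10, y = 4, v = 0.95)))
      rows <- rbind(rows, data.frame(frame = f, x = 10, y = 4))
    }
    if (f <= 14) {                                 # B approaching
      boxes <- c(boxes, list(list(x = xB(f), y = 4, v = 0.05)))
      rows <- rbind(rows, data.frame(frame = f, x = xB(f), y = 4))
    }
    if (f == 15) {                                 # the ambiguous frame
      boxes <- list(list(x = 16, y = 4, v = 0.95),
                    list(x = 16, y = 25, v = 0.05))
      rows <- rbind(data.frame(frame = f, x = 16, y = 4),
                    data.frame(frame = f, x = 16, y = 25))
    }
    frames[[f + 1]] <- mkFrame(boxes)
    rows$w <- w; rows$h <- h; rows$conf <- 1; rows$label <- "person"
    detRows[[f + 1]] <- rows
  }
  dets <- DetectionSet(do.call(rbind, detRows))
  lastA <- bbox(10, 4, w, h); lastB <- bbox(22, 4, w, h)
  bright <- bbox(16, 4, w, h); dark <- bbox(16, 25, w, h)
  straight <- centroidDistance(lastA, bright) + centroidDistance(lastB, dark)
  crossed <- centroidDistance(lastA, dark) + centroidDistance(lastB, bright)
  expect_equal(straight, crossed)               # the distance cost is tied
  ts <- trackDetections(dets, pipelineConfig(tracker = "deepsort"),
                        frames = frames)
  a <- assignments(ts)
  aId <- a$id[a$frame == 0 & a$x == 10]
  expect_identical(a$id[a$frame == 15 & a$y == 4], aId)
})
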