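# Synthetic scenes: textured rectangular sprites bouncing over a textured
# background, one designated high-activity sprite moving faster and
# reversing direction more often than the rest. Sprites carry seeded
# random-noise textures (smoothed, so both flow estimation and
# spatiotemporal derivatives have signal; solid colours would defeat
# gradient-based estimation through the aperture problem) and distinct
# base brightness (so appearance descriptors separate identities). All
# randomness flows through explicit seeds.

#' Describe one sprite of a synthetic scene
#'
#' @param id positive integer identity.
#' @param w,h sprite size in pixels.
#' @param x0,y0 top-left starting position (integer pixels).
#' @param xmin,xmax horizontal travel range: the sprite bounces between
#'   these x offsets at constant speed. A narrow range forces frequent
#'   direction reversals.
#' @param speed horizontal speed in pixels/frame (integer).
#' @param dir initial direction (+1 right, -1 left).
#' @param brightness mean texture intensity in (0, 1).
#' @param textureSeed seed of the sprite's noise texture.
#' @param active whether this is the scene's designated active sprite.
#' @return A \code{SpriteSpec} list.
#' @export
spriteSpec <- function(id, w = 16L, h = 22L, x0 = 0L, y0 = 0L,
                       xmin = 0L, xmax = 100L, speed = 1L, dir = 1L,
                       brightness = 0.5, textureSeed = id,
                       active = FALSE) {
  stopifnot(w > 0, h > 0, speed >= 0, xmin <= x0, x0 <= xmax,
            dir %in% c(-1L, 1L))
  structure(list(id = as.integer(id), w = as.integer(w), h = as.integer(h),
                 x0 = as.integer(x0), y0 = as.integer(y0),
                 xmin = as.integer(xmin), xmax = as.integer(xmax),
                 speed = as.integer(speed), dir = as.integer(dir),
                 brightness = brightness,
                 textureSeed = as.integer(textureSeed),
                 active = isTRUE(active)),
            class = "SpriteSpec")
}

#' Configure a synthetic scene
#'
#' When \code{sprites} is NULL a default scene is drawn from the seed:
#' \code{nSprites} sprites of identical size in separate horizontal lanes,
#' inactive sprites travelling the full frame width at \code{baseSpeed}
#' pixels/frame, and one randomly chosen active sprite at
#' \code{activeFactor} times that speed confined to a narrow travel range
#' so that it reverses direction every few frames.
#'
#' @param frameWidth,frameHeight frame size in pixels (default 160 x 120).
#' @param nFrames number of frames (default 60, minimum 2).
#' @param sprites list of [spriteSpec()] objects (exactly one active), or
#'   NULL for the default scene.
#' @param nSprites number of sprites in the default scene (5).
#' @param baseSpeed inactive sprite speed in pixels/frame (1).
#' @param activeFactor active-to-inactive speed ratio (3).
#' @param noiseSd per-pixel Gaussian noise standard deviation (0.01).
#' @param backgroundSeed seed of the background texture.
#' @param seed master seed for sprite placement and frame noise.
#' @return A \code{SceneConfig} list, validated so that every sprite stays
#'   inside the frame at all times.
#' @export
sceneConfig <- function(frameWidth = 160L, frameHeight = 120L,
                        nFrames = 60L, sprites = NULL, nSprites = 5L,
                        baseSpeed = 1L, activeFactor = 3L, noiseSd = 0.01,
                        backgroundSeed = 1L, seed = 1L) {
  stopifnot(nFrames >= 2L, frameWidth > 0L, frameHeight > 0L)
  if (is.null(sprites))
    sprites <- withSeed(seed + 1000L,
                        defaultSprites(frameWidth, frameHeight, nSprites,
                                       baseSpeed, activeFactor))
  if (sum(vapply(sprites, `[[`, logical(1), "active")) != 1L)
    stop("exactly one sprite must be active")
  cfg <- structure(list(frameWidth = as.integer(frameWidth),
                        frameHeight = as.integer(frameHeight),
                        nFrames = as.integer(nFrames), sprites = sprites,
                        noiseSd = noiseSd,
                        backgroundSeed = as.integer(backgroundSeed),
                        seed = as.integer(seed)),
                   class = "SceneConfig")
  tr <- sceneTrajectories(cfg)
  if (any(tr$x < 0 | tr$y < 0 | tr$x + tr$w > frameWidth |
          tr$y + tr$h > frameHeight))
    stop("a sprite leaves the frame bounds; adjust the scene configuration")
  cfg
}

defaultSprites <- function(frameWidth, frameHeight, nSprites, baseSpeed,
                           activeFactor) {
  # person-like aspect with per-sprite apparent size (distinct areas make
  # the area term of the tracking cost informative, as for real subjects
  # at different distances from the camera); lanes keep a clear vertical
  # gap. Size order is shuffled so size does not encode the lane.
  ws <- as.integer(round(seq(11L, 17L, length.out = nSprites)))
  hs <- as.integer(round(1.3 * ws))
  ord <- sample.int(nSprites)
  ws <- ws[ord]; hs <- hs[ord]
  laneGap <- (frameHeight - sum(hs)) %/% (nSprites + 1L)
  if (laneGap < 1L) stop("too many sprites for the frame height")
  y0 <- laneGap + c(0L, cumsum(hs + laneGap))[seq_len(nSprites)]
  activeIdx <- sample.int(nSprites, 1L)
  bright <- seq(0.15, 0.9, length.out = nSprites)
  lapply(seq_len(nSprites), function(i) {
    active <- i == activeIdx
    speed <- if (active) as.integer(baseSpeed * activeFactor)
             else as.integer(baseSpeed)
    w <- ws[i]
    if (active) {
      # narrow travel range => a direction reversal every ~10 frames
      span <- 10L * speed
      x0 <- sample.int(frameWidth - w - span, 1L) - 1L
      xmin <- x0
      xmax <- x0 + span
    } else {
      xmin <- 0L
      xmax <- frameWidth - w
      x0 <- sample.int(xmax - xmin + 1L, 1L) - 1L
    }
    spriteSpec(id = i, w = w, h = hs[i], x0 = x0, y0 = y0[i],
               xmin = xmin, xmax = xmax, speed = speed,
               dir = sample(c(-1L, 1L), 1L),
               brightness = bright[i], textureSeed = 100L + i,
               active = active)
  })
}

# per-frame integer positions of every sprite (bouncing between xmin/xmax)
sceneTrajectories <- function(cfg) {
  rows <- lapply(cfg$sprites, function(sp) {
    x <- integer(cfg$nFrames)
    d <- sp$dir
    cur <- sp$x0
    for (f in seq_len(cfg$nFrames)) {
      x[f] <- cur
      nxt <- cur + d * sp$speed
      if (nxt > sp$xmax || nxt < sp$xmin) d <- -d
      cur <- min(max(cur + d * sp$speed, sp$xmin), sp$xmax)
    }
    data.frame(frame = seq_len(cfg$nFrames) - 1L, id = sp$id, x = x,
               y = sp$y0, w = sp$w, h = sp$h)
  })
  do.call(rbind, rows)
}

smoothNoiseTexture <- function(nr, nc, seed, base, amp, sigma = 1.5) {
  withSeed(seed, {
    m <- matrix(stats::runif(nr * nc), nr, nc)
    k <- gaussKernel(sigma)
    m <- convDim(convDim(m, k, 1L), k, 2L)
    rng <- range(m)
    base + amp * (2 * (m - rng[1]) / max(rng[2] - rng[1], 1e-12) - 1)
  })
}

#' Generate a synthetic scene
#'
#' Renders the configured sprites over the background for every frame,
#' adds seeded Gaussian pixel noise, and returns the frames together with
#' the full ground truth. Deterministic: the same configuration (including
#' seeds) yields bitwise-identical output.
#'
#' @param cfg a \code{SceneConfig} ([sceneConfig()]).
#' @return List with \code{frames} (list of intensity matrices in
#'   \[0, 1\]) and \code{truth} (a [SceneTruth-class]).
#' @export
generateScene <- function(cfg) {
  stopifnot(inherits(cfg, "SceneConfig"))
  traj <- sceneTrajectories(cfg)
  bg <- smoothNoiseTexture(cfg$frameHeight, cfg$frameWidth,
                           cfg$backgroundSeed, base = 0.45, amp = 0.08)
  tex <- lapply(cfg$sprites, function(sp)
    smoothNoiseTexture(sp$h, sp$w, sp$textureSeed,
                       base = sp$brightness, amp = 0.22))
  names(tex) <- vapply(cfg$sprites, function(sp) as.character(sp$id),
                       character(1))
  frames <- withSeed(cfg$seed, {
    lapply(seq_len(cfg$nFrames) - 1L, function(f) {
      img <- bg
      tf <- traj[traj$frame == f, , drop = FALSE]
      for (i in seq_len(nrow(tf))) {
        r <- tf$y[i] + seq_len(tf$h[i])
        c <- tf$x[i] + seq_len(tf$w[i])
        img[r, c] <- tex[[as.character(tf$id[i])]]
      }
      if (cfg$noiseSd > 0)
        img <- img + matrix(stats::rnorm(length(img), sd = cfg$noiseSd),
                            nrow(img), ncol(img))
      pmin(pmax(img, 0), 1)
    })
  })
  activeId <- vapply(cfg$sprites, `[[`, integer(1), "id")[
    vapply(cfg$sprites, `[[`, logical(1), "active")]
  truth <- new("SceneTruth", boxes = traj, activeId = activeId,
               frameSize = c(cfg$frameWidth, cfg$frameHeight),
               nFrames = cfg$nFrames)
  list(frames = frames, truth = truth)
}

#' Perturb ground-truth boxes into a realistic detection stream
#'
#' Emulates an imperfect detector: each ground-truth box is independently
#' dropped with probability \code{dropoutP}; surviving boxes have both
#' corners jittered with Gaussian noise of sd \code{jitterSd}; a
#' Poisson(\code{fpRate}) number of false-positive boxes is added per
#' frame. Confidences are drawn from \code{confModel}. Deterministic given
#' the seed.
#'
#' @param truth a [SceneTruth-class].
#' @param jitterSd corner jitter standard deviation in pixels (default 1).
#' @param dropoutP per-box dropout probability (default 0.05).
#' @param fpRate mean false positives per frame (default 0.2).
#' @param confModel function \code{f(n, true)} drawing \code{n}
#'   confidences for true (\code{TRUE}) or false (\code{FALSE}) boxes;
#'   default: U(0.6, 1) for true boxes, U(0.3, 0.8) for false ones.
#' @param seed RNG seed.
#' @return A [DetectionSet-class] with \code{id = -1} and label
#'   \code{"person"}.
#' @export
perturbDetections <- function(truth, jitterSd = 1, dropoutP = 0.05,
                              fpRate = 0.2, confModel = NULL, seed = 1L) {
  stopifnot(is(truth, "SceneTruth"), dropoutP >= 0, dropoutP <= 1,
            jitterSd >= 0, fpRate >= 0)
  if (is.null(confModel))
    confModel <- function(n, true)
      if (true) stats::runif(n, 0.6, 1) else stats::runif(n, 0.3, 0.8)
  W <- truth@frameSize[1]
  H <- truth@frameSize[2]
  b <- truth@boxes
  withSeed(seed, {
    keep <- stats::runif(nrow(b)) >= dropoutP
    kept <- b[keep, , drop = FALSE]
    n <- nrow(kept)
    if (n > 0L) {
      x1 <- kept$x + stats::rnorm(n, sd = jitterSd)
      y1 <- kept$y + stats::rnorm(n, sd = jitterSd)
      x2 <- kept$x + kept$w + stats::rnorm(n, sd = jitterSd)
      y2 <- kept$y + kept$h + stats::rnorm(n, sd = jitterSd)
      x1 <- pmin(pmax(x1, 0), W - 2)
      y1 <- pmin(pmax(y1, 0), H - 2)
      out <- data.frame(frame = kept$frame, id = -1L, x = x1, y = y1,
                        w = pmax(x2 - x1, 1), h = pmax(y2 - y1, 1),
                        conf = confModel(n, TRUE), label = "person",
                        stringsAsFactors = FALSE)
      out$w <- pmin(out$w, W - out$x)
      out$h <- pmin(out$h, H - out$y)
    } else {
      out <- emptyDetectionFrame()
    }
    fps <- lapply(sort(unique(b$frame)), function(f) {
      k <- stats::rpois(1L, fpRate)
      if (k == 0L) return(NULL)
      w <- stats::runif(k, 10, 24)
      h <- stats::runif(k, 14, 30)
      data.frame(frame = f, id = -1L,
                 x = stats::runif(k, 0, pmax(W - w, 1)),
                 y = stats::runif(k, 0, pmax(H - h, 1)),
                 w = w, h = h, conf = confModel(k, FALSE),
                 label = "person", stringsAsFactors = FALSE)
    })
    fps <- do.call(rbind, fps)
    DetectionSet(rbind(out, fps))
  })
}

#' Ground-truth-backed activity scorer
#'
#' A test double for a trained active/inactive classifier: scores a query
#' box by its IoU with the active sprite's ground-truth box in that frame
#' (0 when the active sprite is absent).
#'
#' @param truth a [SceneTruth-class].
#' @return Function \code{f(frame, box)} returning a confidence in
#'   \[0, 1\].
#' @export
oracleScorer <- function(truth) {
  stopifnot(is(truth, "SceneTruth"))
  b <- truth@boxes
  act <- b[b$id == truth@activeId, , drop = FALSE]
  function(frame, box) {
    row <- act[act$frame == frame, , drop = FALSE]
    if (nrow(row) == 0L) return(0)
    boxIoU(asBoxMatrix(box), asBoxMatrix(row))
  }
}
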