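# ActiveTracker

Detects the **most active subject** in a multi-subject video sequence from
per-frame bounding-box detections. Given a detection stream (any detector;
a MOT-Challenge-style CSV or in-memory table), the package

1. **filters** detections by confidence (default ≥ 0.55) and class label,
2. **tracks** them into persistent identities — either a Hungarian
   assignment on the cost `w·d(C_prev, C_det) + (1−w)·|P_det − P_prev|`
   (centroid distance, gated at `T = 100` px, plus area difference), or a
   Deep-SORT-style blend `λ·d⁽¹⁾ + (1−λ)·d⁽²⁾` of a squared Mahalanobis
   distance from a Kalman prediction and a cosine appearance distance to a
   gallery of the last 100 unit-norm 128-element descriptors; tracks close
   after `M = 20` consecutive missed frames,
3. **scores activity** of every tracked box per frame: the maximum
   Lucas–Kanade optical-flow magnitude inside the box, the density of
   Harris3D spatiotemporal interest points (`H = det(μ) − k·tr³(μ)`,
   `k = 0.005`), or a pluggable classifier confidence,
4. **ranks and selects**: boxes are ranked by activity within each frame;
   the track most often ranked first (most "wins") is the active subject,
5. **evaluates**: frame-level precision/recall/F1 under a largest-IoU rule
   with a 10% minimum overlap, and a track-level true-positive decision
   (IoU ≥ α in at least a θ fraction of frames; α = θ = 50%) summarised as
   TPR%.

A fully ground-truthed **synthetic scene generator** (textured sprites, one
designated high-activity sprite at 3× speed, seeded detection jitter,
dropout and false positives) makes every stage testable offline — no
dataset or trained network is required anywhere.

## Worked example

```r
library(ActiveTracker)

sc   <- generateScene(sceneConfig(seed = 1))              # 5 sprites, 60 frames
dets <- perturbDetections(sc$truth, jitterSd = 1,         # imperfect detector
                          dropoutP = 0.05, seed = 501)
run  <- runPipeline(sc$frames, dets, pipelineConfig(measure = "of"))
run
#> PipelineRun
#>   tracks: 6 | activity records: 286 | measure: of | tracker: hungarian
#> SelectionResult
#>   active track: 3 (49 win(s) over 60 ranked frame(s))
#>   wins:  1=1 2=10 3=49 4=1 5=0 6=2
```

Track 3 wins 49 of the 60 frames — it is the track of the sprite the
generator designated active (`activeId(sc$truth)` is also 3 here). The
decision is confirmed at track level:

```r
gt <- truthBoxes(sc$truth)
gtActive <- gt[gt$id == activeId(sc$truth), ]
evalTrack(trackBoxes(run@tracks, activeTrack(run)), gtActive)
#> [1] 1          # true positive at alpha = theta = 0.5
head(run@trajectory, 3)   # the selected subject's centroid polyline
#>   frame       cx       cy
#> 1     0 35.58342 62.17964
#> 2     1 38.58558 62.41860
#> 3     2 41.06197 61.98398
```

`run@crops` indexes the selected track's boxes for a thumbnail collage, and
`run@manifest` records the configuration, seed and input hashes under which
the run reproduces bitwise.

A thin command-line wrapper with subcommands `simulate`, `filter`, `track`,
`activity`, `select`, `evaluate` and `run` is installed at
`inst/scripts/activetracker`.

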