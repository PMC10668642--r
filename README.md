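# flocktrack

Quantifying the activity of group-housed animals — ducks, broilers, or any
top-down-filmed pen — from per-frame detector output. Given bounding boxes
(and optionally instance masks) for every video frame, `flocktrack` links
them into identity-labelled trajectories, reduces each animal to a stable
representative point, and summarises a clip by the **single-frame average
displacement (SFAD)**: the mean per-frame Euclidean displacement of tracked
individuals, in pixels/frame. SFAD is the kind of statistic welfare studies
use to compare husbandry treatments (e.g. photoperiod schedules) across pens
and age stages.

The package is aimed at researchers who already have a detector (or want to
prototype without one): a built-in cage-scene simulator generates ground-truth
trajectories, elliptical body masks, and noise-corrupted detections, so the
entire pipeline is testable and calibratable end to end with known answers.

## What's inside

* **Tracker** — tracking-by-detection with a two-tier *confidence cascade*:
  detections with confidence below 0.1 are discarded; those in `[0.1, 0.45)`
  are held back as a low-confidence tier; high-confidence detections
  (`>= 0.45`) are matched to tracks first by IoU and optimal (Hungarian)
  assignment, then the low tier gets a second pass at the leftovers.
  Tracks ride a Kalman constant-velocity model over
  `(xc, yc, w, h, vx, vy, vw, vh)` — width and height live in the state — and
  a track may coast unmatched for up to 30 frames before it is dropped,
  recovering identities across short occlusions.
* **Mask centroids** — image-moment centroid of each detection's binary
  instance mask, `Cx = M10/M00`, `Cy = M01/M00`, transferred to image
  coordinates by `Sx = Zx + Cx`, `Sy = Zy + Cy`; falls back to the box centre
  when no usable mask exists. Mask centroids track the body rather than the
  (posture-sensitive) box.
* **Activity statistic** — per-trajectory step displacements with the 60-frame
  (2 s at 30 fps) validity filter that suppresses fragments born of identity
  switches, pooled into SFAD
  `L = (Σ_k Σ_i d_ki) / (total counted steps)`, plus group and age-stage
  aggregation and comparison arithmetic.
* **Evaluation** — CLEAR-style MOTA,
  `R_MOTA = 1 − (Σ m_t + Σ f_t + Σ s_t) / Σ g_t`
  (misses, false positives, identity switches over ground-truth objects),
  with sticky correspondences and an IoU ≥ 0.5 gate; metric-comparison
  helpers; and partial-convolution FLOPs accounting
  (`h·w·k²·cp²`, a quarter of the channels ⇒ 1/16 of the cost).
* **Simulator** — correlated random walks in a bounded arena (reflective
  walls), oriented elliptical masks, configurable detector noise (misses,
  Poisson false positives, box jitter, two-tier confidence ranges). Defaults
  mirror a 10-animal pen filmed at 30 fps for 6 minutes.
* **I/O** — MOTChallenge text files, PNG mask rasters with an index, CSV/JSON
  reports, a JSON pipeline config, and a CLI (`inst/cli/flocktrack.R`) with
  `simulate / track / centroid / sfad / evaluate / pipeline` subcommands.

## Worked example

```r
library(flocktrack)

cfg   <- scene_config(arena_width = 800, arena_height = 600, n_agents = 5,
                      n_frames = 300, speed_mean = 2, speed_sd = 0.5, seed = 1)
ncfg  <- noise_config(miss_prob = 0.05, fp_rate = 0.2, box_jitter_sd = 1, seed = 2)
scene <- simulate_scene(cfg, ncfg)
scene
#> <scene_truth> 5 agents over 300 frames (arena 800x600 px)
#>   1504 detections (miss_prob 0.05, fp_rate 0.2)

tracks <- track_flock(scene$detections, tracker_config(), n_frames = 300)
tracks
#> <flock_tracks> 5 tracklets, 1437 observations over 300 frames

cents <- centroid_table(tracks, mask_store_scene(scene$truth))
compute_sfad(cents, sfad_config(), video_id = "demo", video_start = 0)
#> <sfad_report demo> SFAD = 1.9862 px/frame (pooled_steps)
#>   5 valid trajectories, 1371 counted steps, 0 excluded

gt <- with(scene$truth$boxes,
           data.frame(frame = frame, id = agent_id, x = x, y = y,
                      w = w, h = h, conf = 1))
mota_eval(gt, as.data.frame(tracks))
#> <mota_report> MOTA = 0.9580
#>   misses 63, false positives 0, switches 0, objects 1500
```

Reading the output: the five animals were configured to move 2 px/frame on
average and the pipeline recovers SFAD = 1.99 px/frame from the noisy
detections; with a 5% per-frame miss rate the tracker drops no identities
(0 switches), and the 63 misses out of 1500 object-frames give MOTA 0.958.
The FP boxes never enter the output because they fall below the
track-spawning confidence and match no track.

Group-level reporting works on any data frame of per-video SFAD values:

```r
cages <- data.frame(photoperiod = rep(c("16L:8D", "12L:12D"), each = 3),
                    L = c(0.856, 0.953, 0.909, 1.002, 0.863, 1.085))
aggregate_sfad(cages, by = "photoperiod")
#>     group n    mean_L mean_L_3dp
#> 1 12L:12D 3 0.9833333      0.983
#> 2  16L:8D 3 0.9060000      0.906
relative_change(0.983, 1.003)   # activity reduction, percent
#> [1] 1.994018
```

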