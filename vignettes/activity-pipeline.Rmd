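---
title: "Measuring group activity from tracked detections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring group activity from tracked detections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flocktrack)
```

`flocktrack` turns per-frame detector output from a fixed top-down camera
into a per-clip activity statistic for group-housed animals. This vignette
explains the models each stage implements, the parameters that matter and
their defaults, the numerical conventions, and what the synthetic validation
does and does not establish about real data.

## The tracking model

Tracking is by detection: the detector proposes boxes with confidence scores
each frame, and the tracker links them across frames. Association is a
two-tier *confidence cascade*:

1. Detections with confidence below `conf_discard = 0.1` are discarded.
2. High-confidence detections (`conf >= conf_high = 0.45`) are matched to all
   live tracks — active, tentative, and lost tracks still inside the
   retention window — by one-to-one assignment minimising `1 − IoU`, gated at
   `iou_min_high = 0.3`.
3. Low-confidence detections (`0.1 <= conf < 0.45`) get a second pass at the
   tracks left unmatched, gated more tightly (`iou_min_low = 0.5`) because
   low-scoring boxes are noisier. This recovers animals whose boxes degrade
   during partial occlusion instead of dropping them.
4. Unmatched high-confidence detections spawn *tentative* tracks, confirmed
   after `confirm_hits = 3` consecutive updates; a tentative track dies on its
   first miss. Only high-confidence detections may found a track — the low
   tier exists to continue identities, not to invent them.
5. An unmatched confirmed track becomes *lost* and coasts on its motion model
   for up to `retention_frames = 30` consecutive frames (one second at
   30 fps); a match inside that window resumes the original identity, the
   31st consecutive miss deletes the track. IDs are assigned in creation
   order and never reused.

The tier boundaries are half-open, `[0.1, 0.45)`, so the partition is
exhaustive: a detection at exactly 0.1 is low-tier and one at exactly 0.45 is
high-tier.

Each track carries a Kalman constant-velocity state
`(xc, yc, w, h, vx, vy, vw, vh)` — box centre, width and height, and their
per-frame velocities. Putting `w` and `h` in the state (rather than an aspect
ratio) keeps box-size estimates stable for small, shape-shifting animal
targets. Noise is scaled to the current box size: per-frame process noise has
standard deviation `process_noise × size` on position/size components (with
velocity components an eighth of that), and the measurement noise standard
deviation is `measurement_noise × size`; both default to 1/20, the customary
scaling for box trackers of this family, and are configurable. Appearance
embeddings and camera-motion compensation are deliberately out of scope: the
camera is fixed, and an appearance model would require a trained network —
association is IoU-only.

Assignments are solved exactly with the Hungarian algorithm (potentials
formulation, O(n³), implemented in the package and verified against
brute-force permutation enumeration in the tests). Rectangular problems are
padded to square with a large constant; gating removes over-threshold pairs
*after* the optimal assignment. Ties are broken deterministically by the
solver's fixed scan order, so tracking runs are reproducible.

## From boxes to representative points

A bounding-box centre moves when the animal changes posture (wing flap,
preening) without the animal going anywhere. When an instance mask is
available the package instead uses the mask's image-moment centroid:

\[ C_x = M_{10}/M_{00}, \quad C_y = M_{01}/M_{00}, \qquad
   S_x = Z_x + C_x, \quad S_y = Z_y + C_y \]

with `M00` the foreground pixel count, `M10`/`M01` the sums of the 0-based
x/y pixel indices, and `(Zx, Zy)` the image coordinates of the mask's box
anchor. Moments are computed over the filled binary mask directly rather than
an extracted contour — for a filled region the two centroids coincide, and
pixel moments avoid contour-orientation pitfalls.

Conventions worth stating precisely:

* The image origin is the top-left corner, x rightward, y downward, 0-based
  pixel indices; pixel `(ix, iy)` has its centre at continuous coordinates
  `(ix, iy)`. Only the sum `Zx + Cx` matters, so any consistent anchor corner
  works; the top-left anchor matches the raster layout.
* A detection with no mask, or a mask with `M00 = 0`, falls back to its box
  centre, flagged `box_center_fallback` and counted in reports. The fallback
  is expressed in the same pixel-index convention as the moment centroid
  (`x + (w−1)/2`, the mean foreground index of a filled box) so a trajectory
  does not jump by half a pixel when a mask drops out.
* Degenerate masks raise a typed condition (`flocktrack_degenerate_mask`)
  rather than dividing by zero.

## The activity statistic

For each valid trajectory the per-frame displacements
`d_i = sqrt((x_i − x_{i−1})² + (y_i − y_{i−1})²)` are collected, and the
single-frame average displacement of a clip is, in the default
`pooled_steps` mode,

\[ L = \frac{\sum_k \sum_i d_{ki}}{\sum_k n_k} \]

— total path length over all valid trajectories divided by the total number
of counted steps. This is a frame-count-weighted mean: an animal tracked for
twice as many frames contributes twice the weight, which makes the statistic
insensitive to how identity switches fragment trajectories (the tests verify
that splitting one long trajectory changes `L` by exactly the lost
inter-piece step, `|L − d|/(n−1)`). A `per_track_mean` mode (equal weight per
trajectory) is provided for sensitivity analysis. A trajectory of `n` points
contributes at most `n − 1` steps; with `consecutive_only` (default), pairs
of points more than one frame apart — tracking gaps — contribute nothing, so
coasting does not fabricate displacement.

Two validity rules clean the input:

* Trajectories shorter than `min_frames = 60` frames (2 s at 30 fps) are
  excluded: fragments this short are typically the residue of identity
  switches, and their step statistics are unreliable.
* Trajectories present from the video's first frame are exempt from the rule
  when a start frame is supplied (they cannot be switch-born); set
  `exempt_initial = FALSE` to apply the rule to every trajectory. Post hoc,
  a genuinely new identity and a switch-born one are indistinguishable, so
  the exemption is the only information actually available.

`L` is reported in pixels/frame; no physical calibration is attempted.
Group summaries are plain arithmetic means of member values (e.g. mean over
a photoperiod group's cages), reported unrounded alongside the conventional
3-decimal rounding; note that a mean like 1.00366… prints as 1.004 under
round-half-even whereas truncation would give 1.003 — the package reports
both the unrounded and rounded values so the choice is visible.
`relative_change(value, reference)` uses the reduction convention
`(reference − value)/reference × 100`. Age-stage binning uses the four closed
ranges 6–13, 14–19, 20–25 and 26–31 days, warning on out-of-range ages.

## Evaluation

Tracking quality is scored CLEAR-style:

\[ R_{MOTA} = 1 - \frac{\sum_t (m_t + f_t + s_t)}{\sum_t g_t} \]

with `m` misses, `f` false positives, `s` identity switches and `g`
ground-truth objects per frame. The correspondence rule (which the formula
itself leaves open) follows the reference conventions: pairs carried over
from the previous frame are kept while they still overlap at IoU ≥ 0.5
(sticky correspondences), remaining objects are matched by optimal assignment
on IoU subject to the same gate, and a switch is charged when a ground-truth
object's matched hypothesis ID differs from its most recent prior match,
including re-acquisition after a gap. MOTA is at most 1 and may be negative.

The module also carries the comparison arithmetic used in model tables —
differences of unit-interval metrics in percentage points, relative gains in
percent — and partial-convolution FLOPs accounting: a convolution applied to
`cp` of `c` channels costs `h·w·k²·cp²`, a fraction `(cp/c)²` of the regular
convolution; at the customary `cp = c/4`, 1/16.

## The synthetic scene generator

No public dataset pairs top-down pen video with ground-truth identities and
masks, so validation uses a simulator whose answers are known by
construction:

* **Motion** — a correlated random walk: per frame, each heading receives a
  Gaussian turn with standard deviation `(1 − heading_persistence)·π` and a
  step of length `|Normal(speed_mean, speed_sd)|` (truncated at zero) is
  taken; walls reflect (position folded, heading mirrored). The turn-angle
  formulation is used (rather than shrinking the heading itself toward zero)
  because it is rotation-invariant: behaviour cannot depend on compass
  direction. The configured `speed_mean` is therefore the known value SFAD
  should recover — the basis of the parameter-recovery tests.
* **Bodies** — ellipses with semi-axes `body_semi_axes` (default 24 × 14 px)
  oriented along the heading; a mask pixel is foreground iff its centre lies
  inside the ellipse, and the ground-truth box is the mask's tight bounding
  box. Rasterised mask centroids sit within half a pixel of the true centre.
* **Detector noise** — each true object is missed with probability
  `miss_prob`; surviving boxes get zero-mean Gaussian jitter
  (`box_jitter_sd`) and a confidence uniform on `conf_tp_range`
  (default `[0.45, 1]`); `Poisson(fp_rate)` false boxes per frame carry
  confidences from `conf_fp_range` (default `[0.05, 0.5]`). The defaults
  straddle both cascade tiers so the low-confidence pass is exercised. True
  detections keep a reference to their instance mask, anchored at the mask's
  own (un-jittered) origin — mirroring the motivation for mask centroids,
  which is that segmentation is more stable than the regression box. No
  published error rates exist for this detector class on pen video, so the
  noise defaults are plausible placeholders, deliberately tunable.
* **Defaults** mirror the recording setup the pipeline targets: 10 animals
  per pen, 30 fps, 6-minute clips (10 800 frames). Agents never enter or
  leave the scene. No collision avoidance is modelled, so animals may overlap
  — which is exactly what produces the occlusion stress the cascade must
  survive; clustered resting behaviour is otherwise not modelled.

Everything is reproducible from two seeds (motion and noise), and
determinism is tested, including bitwise-identical pipeline artifacts.

## Numerical and scale choices

* Boxes are `(x, y, w, h)`, top-left anchored, 0-based, half-open; boxes that
  merely share an edge have IoU 0. On-disk MOTChallenge files are 1-based in
  the frame column; the reader/writer is the only place the offset is
  applied. Coordinates round-trip at 6 decimal places.
* Demonstration problem sizes: the validation suite uses clips of 80–600
  frames and parameter-recovery scenes of 10 agents × 600 frames (well
  separated by construction: a 5 × 2 starting grid with 600 px spacing and
  weakly persistent motion, so identities are unambiguous and MOTA = 1 with
  zero switches is the correct answer). The 10 000-step single-agent run
  checks the empirical mean step length to 1%. These sizes make the whole
  suite run in about a minute while leaving Monte-Carlo error well below the
  asserted tolerances; the simulator's own defaults remain full 6-minute
  clips.
* SFAD recovery tolerances: 5% on noiseless scenes, 10% at `miss_prob =
  0.05`. Rasterised-centroid jitter adds a small positive bias to step
  lengths (≈ σ²/s for jitter σ on steps of length s — well under 1% at the
  default geometry), which these bands absorb.

## Known limitations

* Association is IoU-only; two animals that overlap heavily for longer than
  the 30-frame retention window can swap or lose identities, as the
  occlusion-heavy simulations show. An appearance-similarity hook would
  require a trained embedding and is out of scope.
* The simulator does not model huddling, lighting changes, molting, or any
  photometric effect — it validates the *geometry and statistics* of the
  pipeline (association logic, centroid math, SFAD estimands), not detector
  robustness. Passing tests say nothing about how a real detector behaves in
  dim pens.
* Masks ride along with detections one-to-one; running detection and
  segmentation as independent models with a mask–box linking step is not
  modelled.
* SFAD is reported in pixels/frame. Comparisons across cameras assume equal
  mounting height and optics; no metric calibration is attempted.
* Group comparisons stop at descriptive aggregation; the package deliberately
  performs no hypothesis testing between treatment groups.
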