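#' Scene configuration for the synthetic cage simulator
#'
#' Describes a top-down view of a single pen: arena size in pixels, the number
#' of animals, clip length, and the correlated-random-walk motion parameters.
#' Defaults mirror a common group-housing recording setup: 10 animals per pen
#' filmed at 30 frames/s in 6-minute clips (10800 frames).
#'
#' Motion follows a correlated random walk: each frame an agent turns by a
#' Gaussian angle with standard deviation `(1 - heading_persistence) * pi`
#' radians and moves one step whose length is drawn from
#' `Normal(speed_mean, speed_sd)` truncated at zero. `heading_persistence = 1`
#' gives straight-line motion, `0` gives near-uniform turning. Bodies are
#' ellipses with semi-axes `body_semi_axes` (pixels), oriented along the
#' heading.
#'
#' @param arena_width,arena_height Arena size in pixels. Must exceed four times
#'   the larger body semi-axis so that agents fit with room to move.
#' @param n_agents Number of animals in the pen.
#' @param n_frames Number of frames to simulate.
#' @param fps Frame rate (frames per second), used only for time conversions.
#' @param body_semi_axes Length-2 numeric, semi-major and semi-minor axes of
#'   the elliptical body, in pixels.
#' @param speed_mean,speed_sd Per-frame step-length distribution (pixels/frame).
#' @param heading_persistence Directional persistence in `[0, 1]`.
#' @param seed Integer seed driving placement and motion.
#' @return An object of class `scene_config` (a validated list).
#' @seealso [simulate_scene()], [noise_config()]
#' @examples
#' cfg <- scene_config(n_agents = 3, n_frames = 100, arena_width = 300,
#'                     arena_height = 200)
#' @export
scene_config <- function(arena_width = 640, arena_height = 480,
                         n_agents = 10, n_frames = 10800, fps = 30,
                         body_semi_axes = c(24, 14),
                         speed_mean = 2, speed_sd = 0.5,
                         heading_persistence = 0.9, seed = 1L) {
  if (!is_count(n_agents, 1L)) stopf("n_agents must be a positive integer")
  if (!is_count(n_frames, 1L)) stopf("n_frames must be a positive integer")
  if (!is_num1(fps) || fps <= 0) stopf("fps must be positive")
  if (!is.numeric(body_semi_axes) || length(body_semi_axes) != 2L ||
      any(body_semi_axes < 1)) {
    stopf("body_semi_axes must be two values >= 1 pixel")
  }
  r <- max(body_semi_axes)
  if (!is_num1(arena_width) || !is_num1(arena_height) ||
      arena_width <= 4 * r || arena_height <= 4 * r) {
    stopf("arena dimensions must exceed 4 * max(body_semi_axes) = %g px", 4 * r)
  }
  if (!is_num1(speed_mean) || speed_mean < 0) stopf("speed_mean must be >= 0")
  if (!is_num1(speed_sd) || speed_sd < 0) stopf("speed_sd must be >= 0")
  if (!is_prob(heading_persistence)) {
    stopf("heading_persistence must lie in [0, 1]")
  }
  structure(list(
    arena_width = arena_width, arena_height = arena_height,
    n_agents = as.integer(n_agents), n_frames = as.integer(n_frames),
    fps = fps, body_semi_axes = as.numeric(body_semi_axes),
    speed_mean = speed_mean, speed_sd = speed_sd,
    heading_persistence = heading_persistence, seed = as.integer(seed)
  ), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "<scene_config> %d agents, %d frames @ %g fps, arena %gx%g px\n",
    x$n_agents, x$n_frames, x$fps, x$arena_width, x$arena_height))
  cat(sprintf("  body %g x %g px; speed %g +/- %g px/frame; persistence %g; seed %d\n",
              x$body_semi_axes[1], x$body_semi_axes[2],
              x$speed_mean, x$speed_sd, x$heading_persistence, x$seed))
  invisible(x)
}

#' Detector-noise configuration
#'
#' Parameters of the synthetic "detector" that corrupts ground-truth boxes into
#' detections: per-object miss probability, Poisson false-positive rate, box
#' jitter, and the confidence ranges assigned to true and false detections.
#' Defaults span both tiers of the tracker's confidence cascade (0.1 / 0.45):
#' true positives draw confidence from `[0.45, 1]`, false positives from
#' `[0.05, 0.5]`.
#'
#' @param miss_prob Probability that a true object is missed, per frame.
#' @param fp_rate Expected number of false-positive boxes per frame (Poisson).
#' @param box_jitter_sd Standard deviation (pixels) of zero-mean Gaussian noise
#'   added to each box coordinate and size.
#' @param conf_tp_range,conf_fp_range Length-2 `(lo, hi)` uniform confidence
#'   ranges for true and false detections.
#' @param seed Integer seed for the noise stream (independent of the motion
#'   seed).
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(miss_prob = 0.02, fp_rate = 0.1, box_jitter_sd = 1,
                         conf_tp_range = c(0.45, 1),
                         conf_fp_range = c(0.05, 0.5), seed = 2L) {
  if (!is_prob(miss_prob)) stopf("miss_prob must lie in [0, 1]")
  if (!is_num1(fp_rate) || fp_rate < 0) stopf("fp_rate must be >= 0")
  if (!is_num1(box_jitter_sd) || box_jitter_sd < 0) {
    stopf("box_jitter_sd must be >= 0")
  }
  chk_range <- function(r, nm) {
    if (!is.numeric(r) || length(r) != 2L || r[1] > r[2] ||
        any(r < 0) || any(r > 1)) {
      stopf("%s must be an ordered (lo, hi) pair within [0, 1]", nm)
    }
  }
  chk_range(conf_tp_range, "conf_tp_range")
  chk_range(conf_fp_range, "conf_fp_range")
  structure(list(
    miss_prob = miss_prob, fp_rate = fp_rate, box_jitter_sd = box_jitter_sd,
    conf_tp_range = as.numeric(conf_tp_range),
    conf_fp_range = as.numeric(conf_fp_range), seed = as.integer(seed)
  ), class = "noise_config")
}

# margin keeping the whole body (any orientation) inside the arena
.arena_margin <- function(config) max(config$body_semi_axes) + 1

# truncated-at-zero normal step lengths
.draw_speeds <- function(n, config) {
  pmax(0, stats::rnorm(n, config$speed_mean, config$speed_sd))
}

#' Place agents in the arena without overlap
#'
#' Rejection-samples `n_agents` centres so that every pairwise distance is at
#' least `2 * max(body_semi_axes)` and every body lies fully inside the arena.
#' Headings are uniform on `[0, 2*pi)`. Deterministic given `config$seed`.
#'
#' @param config A [scene_config()].
#' @param max_tries Placement attempts per agent before giving up.
#' @return A data frame with one row per agent: `agent_id`, `x`, `y`,
#'   `heading`, `speed`.
#' @export
init_scene <- function(config, max_tries = 1000L) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  n <- config$n_agents
  m <- .arena_margin(config)
  min_sep <- 2 * max(config$body_semi_axes)
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, m, config$arena_width - 1 - m)
      cy <- stats::runif(1, m, config$arena_height - 1 - m)
      if (i == 1L ||
          all((xs[seq_len(i - 1)] - cx)^2 + (ys[seq_len(i - 1)] - cy)^2 >=
              min_sep^2)) {
        xs[i] <- cx; ys[i] <- cy; placed <- TRUE; break
      }
    }
    if (!placed) {
      stopf("could not place %d non-overlapping agents in a %g x %g arena",
            n, config$arena_width, config$arena_height)
    }
  }
  data.frame(
    agent_id = seq_len(n),
    x = xs, y = ys,
    heading = stats::runif(n, 0, 2 * pi),
    speed = .draw_speeds(n, config)
  )
}

# Reflect positions into [lo, hi]; returns folded position and whether the
# travel direction along this axis ends up flipped (odd number of bounces).
.reflect_axis <- function(p, lo, hi) {
  span <- hi - lo
  q <- (p - lo) %% (2 * span)
  flip <- q > span
  list(pos = ifelse(flip, 2 * span - q, q) + lo, flip = flip)
}

#' Advance agent poses by one frame
#'
#' Correlated-random-walk update: each heading receives a Gaussian turn with
#' standard deviation `(1 - heading_persistence) * pi`, a fresh step length is
#' drawn around `speed_mean`, and positions advance along the heading. Agents
#' reaching the arena boundary are reflected (position folded back, heading
#' mirrored), so the body always stays inside the arena. Consumes the global
#' RNG stream; callers wanting reproducibility seed it (as [simulate_scene()]
#' does).
#'
#' @param poses Data frame from [init_scene()] or a previous step.
#' @param config A [scene_config()].
#' @return Updated poses, same shape and agent order.
#' @export
step_motion <- function(poses, config) {
  stopifnot(inherits(config, "scene_config"))
  n <- nrow(poses)
  turn_sd <- (1 - config$heading_persistence) * pi
  heading <- (poses$heading + stats::rnorm(n, 0, turn_sd)) %% (2 * pi)
  speed <- .draw_speeds(n, config)
  x <- poses$x + speed * cos(heading)
  y <- poses$y + speed * sin(heading)
  m <- .arena_margin(config)
  rx <- .reflect_axis(x, m, config$arena_width - 1 - m)
  ry <- .reflect_axis(y, m, config$arena_height - 1 - m)
  # mirror the heading where an odd number of bounces occurred
  hx <- ifelse(rx$flip, pi - heading, heading)
  heading <- ifelse(ry$flip, -hx, hx) %% (2 * pi)
  data.frame(agent_id = poses$agent_id, x = rx$pos, y = ry$pos,
             heading = heading, speed = speed)
}

# Rasterize one oriented ellipse. Pixel (ix, iy), 0-based, has its centre at
# continuous coordinates (ix, iy); a pixel is foreground iff its centre lies
# inside the ellipse. Returns the tight mask grid, its image-frame origin, and
# the tight bounding box (tlwh, half-open).
.render_ellipse <- function(cx, cy, heading, a, b) {
  ch <- cos(heading); sh <- sin(heading)
  ex <- sqrt((a * ch)^2 + (b * sh)^2)
  ey <- sqrt((a * sh)^2 + (b * ch)^2)
  xs <- floor(cx - ex):ceiling(cx + ex)
  ys <- floor(cy - ey):ceiling(cy + ey)
  dx <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  dy <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
  u <- (dx * ch + dy * sh) / a
  v <- (-dx * sh + dy * ch) / b
  g <- (u * u + v * v) <= 1
  rows <- which(rowSums(g) > 0L)
  cols <- which(colSums(g) > 0L)
  grid <- matrix(as.integer(g[rows, cols, drop = FALSE]),
                 nrow = length(rows))
  origin <- c(xs[cols[1]], ys[rows[1]])
  list(grid = grid, origin = origin,
       box = c(origin[1], origin[2], length(cols), length(rows)))
}

#' Render one frame of ground truth
#'
#' Rasterizes each agent's oriented elliptical body: the mask contains exactly
#' the pixels whose centres fall inside the ellipse, and the box is the tight
#' axis-aligned bounding box of the mask (`(x, y, w, h)`, 0-based, half-open).
#'
#' @param poses Pose data frame for one frame.
#' @param config A [scene_config()].
#' @return A list with one element per agent: `agent_id`, `box`, `mask`
#'   (0/1 integer matrix, rows = y), `origin` (image coordinates of the mask
#'   grid's top-left pixel).
#' @export
render_frame <- function(poses, config) {
  stopifnot(inherits(config, "scene_config"))
  a <- config$body_semi_axes[1]; b <- config$body_semi_axes[2]
  lapply(seq_len(nrow(poses)), function(i) {
    r <- .render_ellipse(poses$x[i], poses$y[i], poses$heading[i], a, b)
    list(agent_id = poses$agent_id[i], box = r$box,
         mask = r$grid, origin = r$origin)
  })
}

#' Corrupt one frame of ground truth into detections
#'
#' Emulates an imperfect detector: each true object is dropped with probability
#' `miss_prob`, surviving boxes are perturbed by zero-mean Gaussian jitter and
#' given a confidence drawn uniformly from `conf_tp_range`, and
#' `Poisson(fp_rate)` false boxes (uniform position, body-scale size, maskless,
#' confidence from `conf_fp_range`) are appended. True detections keep a
#' `mask_id` referencing the agent's instance mask. Consumes the global RNG
#' stream.
#'
#' @param truth_frame Output of [render_frame()].
#' @param noise A [noise_config()].
#' @param config The [scene_config()] (for arena and body dimensions).
#' @param frame 0-based frame index stamped onto the detections.
#' @return A data frame with columns `frame`, `x`, `y`, `w`, `h`, `conf`,
#'   `mask_id` (NA for false positives).
#' @export
corrupt_detections <- function(truth_frame, noise, config, frame = 0L) {
  stopifnot(inherits(noise, "noise_config"), inherits(config, "scene_config"))
  keep <- stats::runif(length(truth_frame)) >= noise$miss_prob
  rows <- lapply(which(keep), function(i) {
    obj <- truth_frame[[i]]
    jit <- stats::rnorm(4, 0, noise$box_jitter_sd)
    data.frame(
      frame = frame,
      x = obj$box[1] + jit[1], y = obj$box[2] + jit[2],
      w = max(1, obj$box[3] + jit[3]), h = max(1, obj$box[4] + jit[4]),
      conf = stats::runif(1, noise$conf_tp_range[1], noise$conf_tp_range[2]),
      mask_id = sprintf("%d_%d", frame, obj$agent_id),
      stringsAsFactors = FALSE
    )
  })
  n_fp <- stats::rpois(1, noise$fp_rate)
  if (n_fp > 0) {
    ab <- config$body_semi_axes
    fp <- lapply(seq_len(n_fp), function(j) {
      w <- 2 * ab[1] * stats::runif(1, 0.5, 1.5)
      h <- 2 * ab[2] * stats::runif(1, 0.5, 1.5)
      data.frame(
        frame = frame,
        x = stats::runif(1, 0, config$arena_width - w),
        y = stats::runif(1, 0, config$arena_height - h),
        w = w, h = h,
        conf = stats::runif(1, noise$conf_fp_range[1], noise$conf_fp_range[2]),
        mask_id = NA_character_,
        stringsAsFactors = FALSE
      )
    })
    rows <- c(rows, fp)
  }
  if (length(rows) == 0L) return(.empty_detections())
  do.call(rbind, rows)
}

.empty_detections <- function() {
  data.frame(frame = integer(), x = numeric(), y = numeric(), w = numeric(),
             h = numeric(), conf = numeric(), mask_id = character(),
             stringsAsFactors = FALSE)
}

#' Simulate a full cage scene with detector noise
#'
#' Runs [init_scene()] (unless initial poses are supplied), advances the
#' correlated random walk for `n_frames` frames, rasterizes ground-truth boxes,
#' and corrupts each frame into detections. The motion stream is seeded from
#' `config$seed` and the noise stream from `noise$seed`, so results are fully
#' reproducible from the two configurations.
#'
#' @param config A [scene_config()].
#' @param noise A [noise_config()].
#' @param init_poses Optional pose data frame overriding random placement
#'   (useful for constructing provably well-separated scenes).
#' @return A list of class `flock_scene` with elements
#'   * `truth`: a `scene_truth` object — `config`, per-frame `poses`
#'     (data frame with a 0-based `frame` column) and tight ground-truth
#'     `boxes`;
#'   * `detections`: one data frame of noisy detections across all frames.
#'   Instance masks are not stored; [mask_store_scene()] re-renders them on
#'   demand from the truth poses.
#' @examples
#' sc <- simulate_scene(scene_config(n_agents = 2, n_frames = 5,
#'                                   arena_width = 200, arena_height = 200),
#'                      noise_config(miss_prob = 0, fp_rate = 0))
#' nrow(sc$truth$boxes)   # 2 agents x 5 frames
#' @export
simulate_scene <- function(config, noise, init_poses = NULL) {
  stopifnot(inherits(config, "scene_config"), inherits(noise, "noise_config"))
  nf <- config$n_frames; n <- config$n_agents

  # --- motion (seeded by config$seed) ---
  poses <- if (is.null(init_poses)) {
    init_scene(config)
  } else {
    set.seed(config$seed)
    init_poses
  }
  pose_list <- vector("list", nf)
  pose_list[[1]] <- poses
  if (nf > 1) {
    for (f in 2:nf) {
      poses <- step_motion(poses, config)
      pose_list[[f]] <- poses
    }
  }
  all_poses <- do.call(rbind, pose_list)
  all_poses <- cbind(frame = rep(0:(nf - 1), each = n), all_poses)

  # --- rasterize truth boxes and corrupt into detections ---
  set.seed(noise$seed)
  box_list <- vector("list", nf)
  det_list <- vector("list", nf)
  for (f in seq_len(nf)) {
    tf <- render_frame(pose_list[[f]], config)
    bx <- t(vapply(tf, function(o) o$box, numeric(4)))
    box_list[[f]] <- data.frame(
      frame = f - 1L, agent_id = vapply(tf, function(o) o$agent_id, numeric(1)),
      x = bx[, 1], y = bx[, 2], w = bx[, 3], h = bx[, 4]
    )
    det_list[[f]] <- corrupt_detections(tf, noise, config, frame = f - 1L)
  }
  truth <- structure(
    list(config = config, poses = all_poses, boxes = do.call(rbind, box_list)),
    class = "scene_truth"
  )
  structure(list(truth = truth, detections = do.call(rbind, det_list),
                 noise = noise),
            class = "flock_scene")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d agents over %d frames (arena %gx%g px)\n",
              x$config$n_agents, x$config$n_frames,
              x$config$arena_width, x$config$arena_height))
  invisible(x)
}

#' @export
print.flock_scene <- function(x, ...) {
  print(x$truth)
  cat(sprintf("  %d detections (miss_prob %g, fp_rate %g)\n",
              nrow(x$detections), x$noise$miss_prob, x$noise$fp_rate))
  invisible(x)
}

#' Plot simulated ground-truth trajectories
#'
#' @param x A `scene_truth` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scene_truth <- function(x, ...) {
  p <- x$poses
  graphics::plot(NA, xlim = c(0, x$config$arena_width),
                 ylim = rev(c(0, x$config$arena_height)),
                 xlab = "x (px)", ylab = "y (px)",
                 main = "Ground-truth trajectories", asp = 1, ...)
  cols <- grDevices::rainbow(x$config$n_agents)
  for (id in unique(p$agent_id)) {
    pi_ <- p[p$agent_id == id, ]
    graphics::lines(pi_$x, pi_$y, col = cols[id])
  }
  invisible(x)
}
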