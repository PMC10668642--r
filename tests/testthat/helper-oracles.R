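# Independent oracles and fixture builders used across the suite.

# Brute-force optimal assignment cost: enumerate all n! permutations.
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

bf_assignment_cost <- function(cost) {
  n <- nrow(cost)
  min(vapply(all_perms(seq_len(n)),
             function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

# Brute-force centroid: arithmetic mean of foreground 0-based pixel indices.
pixel_mean_centroid <- function(grid) {
  idx <- which(grid == 1L, arr.ind = TRUE)
  c(mean(idx[, "col"]) - 1, mean(idx[, "row"]) - 1)
}

# Random binary mask with at least one foreground pixel.
random_mask <- function(nr, nc, p = 0.4) {
  g <- matrix(as.integer(stats::runif(nr * nc) < p), nr, nc)
  if (sum(g) == 0L) g[sample(length(g), 1L)] <- 1L
  g
}

# A provably well-separated 10-agent scene: agents start on a 5 x 2 grid with
# 600 px spacing in a large arena; slow, weakly persistent motion keeps them
# hundreds of pixels apart for the whole clip.
well_separated_scene <- function(n_frames, miss_prob = 0, fp_rate = 0,
                                 box_jitter_sd = 0, scene_seed = 11L,
                                 noise_seed = 12L, speed_mean = 2,
                                 speed_sd = 0.2) {
  cfg <- scene_config(arena_width = 3100, arena_height = 1300, n_agents = 10,
                      n_frames = n_frames, body_semi_axes = c(24, 14),
                      speed_mean = speed_mean, speed_sd = speed_sd,
                      heading_persistence = 0.5, seed = scene_seed)
  ncfg <- noise_config(miss_prob = miss_prob, fp_rate = fp_rate,
                       box_jitter_sd = box_jitter_sd, seed = noise_seed)
  grid <- expand.grid(x = 300 + 600 * (0:4), y = 350 + 600 * (0:1))
  init <- data.frame(agent_id = 1:10, x = grid$x, y = grid$y,
                     heading = seq(0, 2 * pi, length.out = 11)[1:10],
                     speed = speed_mean)
  list(cfg = cfg, noise = ncfg,
       scene = simulate_scene(cfg, ncfg, init_poses = init))
}

truth_as_gt <- function(truth) {
  with(truth$boxes, data.frame(frame = frame, id = agent_id, x = x, y = y,
                               w = w, h = h, conf = 1))
}

# Mean ground-truth per-frame displacement, straight from agent centres.
truth_mean_step <- function(truth) {
  steps <- unlist(lapply(split(truth$poses, truth$poses$agent_id), function(p) {
    p <- p[order(p$frame), ]
    sqrt(diff(p$x)^2 + diff(p$y)^2)
  }))
  mean(steps)
}

# Exhaustive CLEAR matching oracle for one frame (no history): over all
# injective gt -> hyp mappings with IoU >= thr, pick maximum cardinality, then
# maximum total IoU; returns the miss and false-positive counts.
bf_match_counts <- function(gt, hyp, thr = 0.5) {
  iou <- iou_matrix(gt[, c("x", "y", "w", "h")], hyp[, c("x", "y", "w", "h")])
  ng <- nrow(gt); nh <- nrow(hyp)
  best <- list(card = -1L, iou = -Inf)
  recurse <- function(i, used, card, tot) {
    if (i > ng) {
      if (card > best$card || (card == best$card && tot > best$iou)) {
        best <<- list(card = card, iou = tot)
      }
      return(invisible())
    }
    recurse(i + 1L, used, card, tot)  # gt i unmatched
    for (j in seq_len(nh)) {
      if (!used[j] && iou[i, j] >= thr) {
        used[j] <- TRUE
        recurse(i + 1L, used, card + 1L, tot + iou[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nh), 0L, 0)
  list(m = ng - best$card, f = nh - best$card)
}
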