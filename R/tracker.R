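#' Tracker configuration
#'
#' Parameters of the two-tier confidence-cascade tracker. Detections below
#' `conf_discard` are dropped outright; those in `[conf_discard, conf_high)`
#' form the low-confidence tier used only in the second association pass;
#' those at or above `conf_high` form the high-confidence tier matched first.
#' A track left unmatched may coast for up to `retention_frames` consecutive
#' frames before being discarded; a detection re-matching it within that
#' window resumes the original identity.
#'
#' @param conf_discard Confidence below which detections are discarded
#'   (default 0.1).
#' @param conf_high Boundary between the low- and high-confidence tiers
#'   (default 0.45). Both boundaries follow the half-open convention
#'   `[conf_discard, conf_high)` for the low tier.
#' @param retention_frames Maximum consecutive unmatched frames before a lost
#'   track is removed (default 30; the 31st consecutive miss deletes).
#' @param iou_min_high Minimum IoU for a first-pass (high-confidence) match.
#' @param iou_min_low Minimum IoU for a second-pass (low-confidence) match;
#'   tighter by default to limit false matches from noisy boxes.
#' @param init_conf_min Minimum confidence for an unmatched detection to spawn
#'   a new track (defaults to `conf_high`).
#' @param confirm_hits Consecutive updates before a tentative track is
#'   confirmed; tentative tracks are dropped on their first miss.
#' @param process_noise,measurement_noise Kalman noise scales, expressed as a
#'   fraction of the current box size (per-frame motion std and measurement
#'   std respectively).
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(conf_discard = 0.1, conf_high = 0.45,
                           retention_frames = 30L,
                           iou_min_high = 0.3, iou_min_low = 0.5,
                           init_conf_min = conf_high, confirm_hits = 3L,
                           process_noise = 1 / 20, measurement_noise = 1 / 20) {
  if (!is_prob(conf_discard) || !is_prob(conf_high) ||
      conf_discard >= conf_high) {
    stopf("need 0 <= conf_discard < conf_high <= 1")
  }
  if (!is_count(retention_frames, 1L)) stopf("retention_frames must be >= 1")
  for (g in c(iou_min_high, iou_min_low)) {
    if (!is_num1(g) || g <= 0 || g > 1) stopf("IoU gates must lie in (0, 1]")
  }
  if (!is_count(confirm_hits, 1L)) stopf("confirm_hits must be >= 1")
  structure(list(
    conf_discard = conf_discard, conf_high = conf_high,
    retention_frames = as.integer(retention_frames),
    iou_min_high = iou_min_high, iou_min_low = iou_min_low,
    init_conf_min = init_conf_min, confirm_hits = as.integer(confirm_hits),
    process_noise = process_noise, measurement_noise = measurement_noise
  ), class = "tracker_config")
}

#' Split detections into discard / low / high confidence tiers
#'
#' The three tiers are disjoint and cover the input:
#' `conf < conf_discard` is discarded, `conf_discard <= conf < conf_high` is
#' low, `conf >= conf_high` is high (half-open boundary convention, so a
#' detection exactly at 0.1 is low and one exactly at 0.45 is high).
#'
#' @param dets Detection data frame with a `conf` column.
#' @param cfg A [tracker_config()].
#' @return A list with data frames `discarded`, `low`, `high`.
#' @export
partition_by_confidence <- function(dets, cfg) {
  stopifnot(inherits(cfg, "tracker_config"), "conf" %in% names(dets))
  list(
    discarded = dets[dets$conf < cfg$conf_discard, , drop = FALSE],
    low = dets[dets$conf >= cfg$conf_discard & dets$conf < cfg$conf_high, ,
               drop = FALSE],
    high = dets[dets$conf >= cfg$conf_high, , drop = FALSE]
  )
}

#' Intersection-over-union of two boxes
#'
#' Boxes are `(x, y, w, h)` with the top-left corner at `(x, y)` and half-open
#' extents, so two boxes sharing only an edge have IoU 0.
#'
#' @param a,b Numeric length-4 boxes.
#' @return IoU in `[0, 1]`.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 0, 10, 10))  # 1/3
#' @export
box_iou <- function(a, b) {
  iou_matrix(matrix(a, nrow = 1), matrix(b, nrow = 1))[1, 1]
}

#' Pairwise IoU matrix between two sets of boxes
#'
#' @param A,B Matrices (or data frames) with columns `x, y, w, h`, one box per
#'   row.
#' @return An `nrow(A) x nrow(B)` matrix of IoU values.
#' @export
iou_matrix <- function(A, B) {
  A <- as.matrix(A[, 1:4, drop = FALSE]); B <- as.matrix(B[, 1:4, drop = FALSE])
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(numeric(0), n, m))
  ax1 <- A[, 1]; ay1 <- A[, 2]; ax2 <- A[, 1] + A[, 3]; ay2 <- A[, 2] + A[, 4]
  bx1 <- B[, 1]; by1 <- B[, 2]; bx2 <- B[, 1] + B[, 3]; by2 <- B[, 2] + B[, 4]
  ix <- outer(ax2, bx2, pmin) - outer(ax1, bx1, pmax)
  ix[ix < 0] <- 0
  iy <- outer(ay2, by2, pmin) - outer(ay1, by1, pmax)
  iy[iy < 0] <- 0
  inter <- ix * iy
  areaA <- A[, 3] * A[, 4]; areaB <- B[, 3] * B[, 4]
  inter / (outer(areaA, areaB, `+`) - inter)
}

## ---- Kalman constant-velocity model over (xc, yc, w, h) ----
## State: (xc, yc, w, h, vx, vy, vw, vh); measurement: (xc, yc, w, h).
## Noise standard deviations scale with the current box width/height, the
## usual practice for box trackers that carry width and height in the state.

.kf_F <- local({
  F <- diag(8)
  F[cbind(1:4, 5:8)] <- 1
  F
})
.kf_H <- cbind(diag(4), matrix(0, 4, 4))

.box_to_z <- function(box) {
  c(box[1] + box[3] / 2, box[2] + box[4] / 2, box[3], box[4])
}
.z_to_box <- function(z) c(z[1] - z[3] / 2, z[2] - z[4] / 2, z[3], z[4])

.kf_size_vec <- function(mean) {
  s <- pmax(mean[3:4], 1)       # (w, h)
  c(s[1], s[2], s[1], s[2])
}

.kf_initiate <- function(box, cfg) {
  z <- .box_to_z(box)
  mean <- c(z, rep(0, 4))
  s <- .kf_size_vec(mean)
  std <- c(2 * cfg$process_noise * s, 10 * (cfg$process_noise / 8) * s)
  list(mean = mean, cov = diag(std^2))
}

#' Kalman prediction step
#'
#' Advances a track's state one frame under the constant-velocity model
#' (`xc += vx`, ..., `h += vh`) and inflates the covariance by box-size-scaled
#' process noise. `frames_since_update` is not modified here; miss-counting is
#' the cascade's job.
#'
#' @param track A track state as produced internally by [track_flock()] (a
#'   list with `mean` and `cov`).
#' @param cfg A [tracker_config()].
#' @return The track with advanced `mean` and `cov`.
#' @export
kalman_predict <- function(track, cfg) {
  s <- .kf_size_vec(track$mean)
  std <- c(cfg$process_noise * s, (cfg$process_noise / 8) * s)
  track$mean <- as.numeric(.kf_F %*% track$mean)
  track$cov <- .kf_F %*% track$cov %*% t(.kf_F) + diag(std^2)
  track
}

#' Kalman correction step
#'
#' Folds a detection's box (converted to centre/size measurement) into the
#' track state, resets the miss counter, increments the hit count, and appends
#' the observation to the track history.
#'
#' @param track A track state (list with `mean`, `cov`, `frames_since_update`,
#'   `hits`, `history`).
#' @param det A one-row detection data frame (`frame, x, y, w, h, conf,
#'   mask_id`).
#' @param cfg A [tracker_config()].
#' @return The updated track.
#' @export
kalman_update <- function(track, det, cfg) {
  z <- .box_to_z(c(det$x, det$y, det$w, det$h))
  s <- .kf_size_vec(track$mean)
  R <- diag((cfg$measurement_noise * s)^2)
  S <- .kf_H %*% track$cov %*% t(.kf_H) + R
  K <- track$cov %*% t(.kf_H) %*% solve(S)
  innov <- z - as.numeric(.kf_H %*% track$mean)
  track$mean <- as.numeric(track$mean + K %*% innov)
  track$mean[3:4] <- pmax(track$mean[3:4], 1e-3)
  track$cov <- (diag(8) - K %*% .kf_H) %*% track$cov
  track$frames_since_update <- 0L
  track$hits <- track$hits + 1L
  track$history[[length(track$history) + 1L]] <- det
  track
}

.track_pred_box <- function(track) .z_to_box(track$mean[1:4])

## ---- linear assignment (Hungarian algorithm, potentials formulation) ----
## Returns, for a square cost matrix, the column assigned to each row so that
## the total cost is minimal. O(n^3); deterministic.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  # potentials u (rows, index i+1 with virtual row 0), v (cols, index j+1
  # with virtual col 0); p[j+1] = row matched to column j
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- which(!used[cols + 1])
      cur <- cost[i0, free] - u[i0 + 1] - v[free + 1]
      upd <- cur < minv[free + 1]
      minv[free[upd] + 1] <- cur[upd]
      way[free[upd] + 1] <- j0
      j1 <- free[which.min(minv[free + 1])]
      delta <- minv[j1 + 1]
      usedj <- which(used)
      u[p[usedj] + 1] <- u[p[usedj] + 1] + delta
      v[usedj] <- v[usedj] - delta
      minv[-usedj] <- minv[-usedj] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  assignment[p[cols + 1]] <- cols
  assignment
}

#' Gated one-to-one assignment between tracks and detections
#'
#' Solves the rectangular linear-assignment problem on a cost matrix
#' (typically `1 - IoU`), then removes matched pairs whose cost exceeds the
#' gate. Rectangular inputs are padded to square with a large constant, so the
#' assignment is globally optimal over real pairs.
#'
#' @param cost Numeric cost matrix, rows = tracks, cols = detections.
#' @param gate Maximum admissible cost for a retained match.
#' @return A list: `matches` (two-column matrix of row/col indices),
#'   `unmatched_rows`, `unmatched_cols`.
#' @export
associate <- function(cost, gate = 1) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) {
    return(list(matches = matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("row", "col"))),
                unmatched_rows = seq_len(n), unmatched_cols = seq_len(m)))
  }
  big <- max(cost[is.finite(cost)], 0) + 1e6
  cost[!is.finite(cost)] <- big
  k <- max(n, m)
  sq <- matrix(big, k, k)
  sq[seq_len(n), seq_len(m)] <- cost
  assign <- solve_assignment(sq)
  rows <- seq_len(n)
  cols <- assign[rows]
  keep <- cols <= m & cost[cbind(rows, pmin(cols, m))] <= gate
  matches <- cbind(row = rows[keep], col = cols[keep])
  list(matches = matches,
       unmatched_rows = setdiff(rows, matches[, "row"]),
       unmatched_cols = setdiff(seq_len(m), matches[, "col"]))
}

.new_track <- function(id, det, cfg) {
  kf <- .kf_initiate(c(det$x, det$y, det$w, det$h), cfg)
  list(track_id = id, mean = kf$mean, cov = kf$cov,
       status = if (cfg$confirm_hits <= 1L) "active" else "tentative",
       confirmed = cfg$confirm_hits <= 1L,
       frames_since_update = 0L, hits = 1L, history = list(det))
}

#' Initialise an empty tracker state
#'
#' @param cfg A [tracker_config()].
#' @return A `tracker_state` list (`tracks`, `archive`, `next_id`).
#' @export
tracker_state <- function(cfg = tracker_config()) {
  structure(list(tracks = list(), archive = list(), next_id = 1L, cfg = cfg),
            class = "tracker_state")
}

#' Advance the tracker by one frame
#'
#' One step of the confidence cascade:
#' (1) predict every live track; (2) associate high-confidence detections with
#' all live tracks (active, tentative, and lost within the retention window)
#' gated at `iou_min_high`; (3) associate low-confidence detections with the
#' tracks left unmatched, gated at `iou_min_low`; (4) unmatched
#' high-confidence detections spawn tentative tracks with fresh IDs;
#' (5) unmatched tracks accrue a miss: tentative tracks are dropped, others
#' become lost and are removed after more than `retention_frames` consecutive
#' misses. A lost track re-matched within the window resumes its original ID.
#'
#' @param state A [tracker_state()].
#' @param dets Detections for this frame (data frame `frame, x, y, w, h, conf,
#'   mask_id`); may have zero rows.
#' @return The updated state.
#' @export
step_tracks <- function(state, dets) {
  stopifnot(inherits(state, "tracker_state"))
  cfg <- state$cfg
  tracks <- lapply(state$tracks, kalman_predict, cfg = cfg)
  tiers <- partition_by_confidence(dets, cfg)

  pred_boxes <- if (length(tracks)) {
    do.call(rbind, lapply(tracks, .track_pred_box))
  } else {
    matrix(numeric(0), 0, 4)
  }

  run_stage <- function(track_idx, det_df, iou_min) {
    if (length(track_idx) == 0L || nrow(det_df) == 0L) {
      return(list(matches = matrix(integer(0), 0, 2,
                                   dimnames = list(NULL, c("row", "col"))),
                  unmatched_rows = seq_along(track_idx),
                  unmatched_cols = seq_len(nrow(det_df))))
    }
    cost <- 1 - iou_matrix(pred_boxes[track_idx, , drop = FALSE],
                           det_df[, c("x", "y", "w", "h"), drop = FALSE])
    associate(cost, gate = 1 - iou_min)
  }

  all_idx <- seq_along(tracks)
  s1 <- run_stage(all_idx, tiers$high, cfg$iou_min_high)
  matched_tracks <- all_idx[s1$matches[, "row"]]
  rem_idx <- setdiff(all_idx, matched_tracks)
  s2 <- run_stage(rem_idx, tiers$low, cfg$iou_min_low)

  apply_match <- function(ti, det) {
    tr <- kalman_update(tracks[[ti]], det, cfg)
    if (tr$status == "tentative" && tr$hits >= cfg$confirm_hits) {
      tr$status <- "active"; tr$confirmed <- TRUE
    } else if (tr$status == "lost") {
      tr$status <- "active"
    }
    tr
  }
  if (nrow(s1$matches)) {
    for (k in seq_len(nrow(s1$matches))) {
      ti <- all_idx[s1$matches[k, "row"]]
      tracks[[ti]] <- apply_match(ti, tiers$high[s1$matches[k, "col"], ,
                                                 drop = FALSE])
    }
  }
  if (nrow(s2$matches)) {
    for (k in seq_len(nrow(s2$matches))) {
      ti <- rem_idx[s2$matches[k, "row"]]
      tracks[[ti]] <- apply_match(ti, tiers$low[s2$matches[k, "col"], ,
                                                drop = FALSE])
    }
  }

  # misses: tentative tracks die immediately; others coast up to the window
  unmatched <- setdiff(rem_idx, rem_idx[s2$matches[, "row"]])
  drop_idx <- integer(0)
  for (ti in unmatched) {
    tr <- tracks[[ti]]
    if (tr$status == "tentative") {
      drop_idx <- c(drop_idx, ti)            # never confirmed: discard quietly
    } else {
      tr$frames_since_update <- tr$frames_since_update + 1L
      tr$status <- "lost"
      if (tr$frames_since_update > cfg$retention_frames) {
        state$archive[[length(state$archive) + 1L]] <- tr
        drop_idx <- c(drop_idx, ti)
      } else {
        tracks[[ti]] <- tr
      }
    }
  }
  if (length(drop_idx)) tracks <- tracks[-drop_idx]

  # births from leftover high-confidence detections
  leftover_high <- s1$unmatched_cols
  if (length(leftover_high)) {
    for (ci in leftover_high) {
      det <- tiers$high[ci, , drop = FALSE]
      if (det$conf >= cfg$init_conf_min) {
        tracks[[length(tracks) + 1L]] <- .new_track(state$next_id, det, cfg)
        state$next_id <- state$next_id + 1L
      }
    }
  }
  state$tracks <- tracks
  state
}

#' Track a detection stream into identity-labelled tracklets
#'
#' Runs the confidence-cascade tracker over all frames (including frames with
#' no detections, which count as misses for every live track) and returns the
#' confirmed tracklets. Output observations are exactly the input detections
#' that were matched — the tracker never emits predicted boxes.
#'
#' @param detections Either a single data frame with a 0-based `frame` column,
#'   or a list of per-frame data frames with strictly increasing frame stamps.
#' @param cfg A [tracker_config()].
#' @param n_frames Optional total frame count (defaults to `max(frame) + 1`);
#'   trailing empty frames still age lost tracks.
#' @return An object of class `flock_tracks`: a list with `tracklets` (each a
#'   list of `track_id` and an observation data frame), `cfg`, and `n_frames`.
#' @examples
#' dets <- data.frame(frame = 0:9, x = (0:9) * 2, y = 0, w = 10, h = 10,
#'                    conf = 0.9, mask_id = NA_character_)
#' tr <- track_flock(dets, tracker_config())
#' length(tr$tracklets)   # 1
#' @export
track_flock <- function(detections, cfg = tracker_config(), n_frames = NULL) {
  stopifnot(inherits(cfg, "tracker_config"))
  if (is.data.frame(detections)) {
    det_df <- detections
  } else if (is.list(detections)) {
    stamps <- vapply(detections, function(d) {
      if (nrow(d) == 0L) NA_real_ else d$frame[1]
    }, numeric(1))
    st <- stamps[!is.na(stamps)]
    if (length(st) > 1L && any(diff(st) <= 0)) {
      stopf("per-frame detection list must have strictly increasing frames")
    }
    det_df <- do.call(rbind, detections)
  } else {
    stopf("detections must be a data frame or a list of per-frame data frames")
  }
  if (is.null(det_df) || nrow(det_df) == 0L) {
    det_df <- .empty_detections()
  }
  if (nrow(det_df) > 0 && any(det_df$frame < 0)) stopf("negative frame index")
  if (!"mask_id" %in% names(det_df)) det_df$mask_id <- NA_character_
  nf <- n_frames %||% (if (nrow(det_df)) max(det_df$frame) + 1L else 0L)
  if (nf == 0L) {
    return(structure(list(tracklets = list(), cfg = cfg, n_frames = 0L),
                     class = "flock_tracks"))
  }

  by_frame <- split(det_df, factor(det_df$frame, levels = 0:(nf - 1)))
  state <- tracker_state(cfg)
  for (f in seq_len(nf)) {
    state <- step_tracks(state, by_frame[[f]])
  }
  finished <- c(state$archive, state$tracks)
  finished <- Filter(function(tr) isTRUE(tr$confirmed), finished)
  tracklets <- lapply(finished, function(tr) {
    obs <- do.call(rbind, tr$history)
    obs <- obs[order(obs$frame), , drop = FALSE]
    rownames(obs) <- NULL
    list(track_id = tr$track_id, obs = obs)
  })
  ids <- vapply(tracklets, function(t) t$track_id, numeric(1))
  tracklets <- tracklets[order(ids)]
  structure(list(tracklets = tracklets, cfg = cfg, n_frames = nf),
            class = "flock_tracks")
}

#' @export
print.flock_tracks <- function(x, ...) {
  nobs <- sum(vapply(x$tracklets, function(t) nrow(t$obs), numeric(1)))
  cat(sprintf("<flock_tracks> %d tracklets, %d observations over %d frames\n",
              length(x$tracklets), nobs, x$n_frames))
  invisible(x)
}

#' @export
summary.flock_tracks <- function(object, ...) {
  lens <- vapply(object$tracklets, function(t) nrow(t$obs), numeric(1))
  out <- data.frame(
    track_id = vapply(object$tracklets, function(t) t$track_id, numeric(1)),
    n_obs = lens,
    start_frame = vapply(object$tracklets, function(t) min(t$obs$frame),
                         numeric(1)),
    end_frame = vapply(object$tracklets, function(t) max(t$obs$frame),
                       numeric(1))
  )
  out
}

#' Flatten tracklets into a MOTChallenge-style data frame
#'
#' @param x A `flock_tracks` object.
#' @param ... Unused.
#' @return A data frame `frame, id, x, y, w, h, conf, mask_id` sorted by frame
#'   then id.
#' @export
as.data.frame.flock_tracks <- function(x, ...) {
  if (length(x$tracklets) == 0L) {
    return(data.frame(frame = integer(), id = integer(), x = numeric(),
                      y = numeric(), w = numeric(), h = numeric(),
                      conf = numeric(), mask_id = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(x$tracklets, function(t) {
    cbind(data.frame(frame = t$obs$frame, id = t$track_id), t$obs[, -1])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$frame, out$id), ]
  rownames(out) <- NULL
  out
}
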