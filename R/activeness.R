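#' SFAD configuration
#'
#' Parameters of the single-frame average displacement (SFAD) statistic.
#' Identity switches during tracking spawn short spurious tracklets; a
#' trajectory shorter than `min_frames` points (default 60 frames = 2 s at
#' 30 fps) is considered invalid and excluded. Displacements are, by default,
#' only counted between strictly consecutive frames, so coasting gaps
#' contribute nothing.
#'
#' @param min_frames Minimum trajectory length in frames (default 60).
#' @param fps Frame rate, for converting the rule to seconds.
#' @param consecutive_only If `TRUE` (default) a displacement is counted only
#'   when the two points are exactly one frame apart.
#' @param denominator_mode `"pooled_steps"` (default): SFAD is the total path
#'   length over all valid trajectories divided by the total number of counted
#'   steps, i.e. a frame-count-weighted mean. `"per_track_mean"`: mean over
#'   trajectories of each trajectory's own mean step length.
#' @param exempt_initial If `TRUE`, trajectories starting at the video's first
#'   frame are exempt from the minimum-length rule (the rule targets tracklets
#'   born of identity switches, which by construction start mid-video); only
#'   applied when a video start frame is supplied to [filter_valid()].
#' @return An object of class `sfad_config`.
#' @export
sfad_config <- function(min_frames = 60L, fps = 30, consecutive_only = TRUE,
                        denominator_mode = c("pooled_steps", "per_track_mean"),
                        exempt_initial = TRUE) {
  if (!is_count(min_frames, 2L)) stopf("min_frames must be an integer >= 2")
  if (!is_num1(fps) || fps <= 0) stopf("fps must be positive")
  denominator_mode <- match.arg(denominator_mode)
  structure(list(min_frames = as.integer(min_frames), fps = fps,
                 consecutive_only = isTRUE(consecutive_only),
                 denominator_mode = denominator_mode,
                 exempt_initial = isTRUE(exempt_initial)),
            class = "sfad_config")
}

#' Assemble centroid rows into per-identity trajectories
#'
#' @param centroids Data frame `frame, track_id, Sx, Sy` (extra columns
#'   ignored). Row order is irrelevant; duplicate `(frame, track_id)` pairs
#'   are an error.
#' @return A list of trajectories, each a list with `track_id`, `points`
#'   (data frame `frame, Sx, Sy` sorted by frame), `start_frame`, `end_frame`.
#' @export
build_trajectories <- function(centroids) {
  req <- c("frame", "track_id", "Sx", "Sy")
  if (!all(req %in% names(centroids))) {
    stopf("centroids must have columns %s", paste(req, collapse = ", "))
  }
  if (anyDuplicated(centroids[, c("frame", "track_id")])) {
    stopf("duplicate (frame, track_id) rows in centroid table")
  }
  if (nrow(centroids) == 0L) return(list())
  split_rows <- split(centroids, centroids$track_id)
  ids <- as.numeric(names(split_rows))
  trajs <- lapply(seq_along(split_rows), function(i) {
    d <- split_rows[[i]]
    d <- d[order(d$frame), c("frame", "Sx", "Sy")]
    rownames(d) <- NULL
    list(track_id = ids[i], points = d,
         start_frame = d$frame[1], end_frame = d$frame[nrow(d)])
  })
  trajs[order(ids)]
}

#' Split trajectories into valid and excluded sets
#'
#' A trajectory with fewer than `min_frames` points is excluded — the rule the
#' activity statistic applies to suppress fragments created by identity
#' switches (60 frames = 2 s at 30 fps). A 59-point trajectory is excluded; a
#' 60-point trajectory is kept. If `video_start` is given and
#' `cfg$exempt_initial` is set, trajectories that begin at the first frame are
#' exempt (they cannot be switch-born fragments).
#'
#' @param trajs List of trajectories from [build_trajectories()].
#' @param cfg An [sfad_config()].
#' @param video_start Optional 0-based first frame of the video.
#' @return A list with `valid` and `excluded` trajectory lists.
#' @export
filter_valid <- function(trajs, cfg = sfad_config(), video_start = NULL) {
  stopifnot(inherits(cfg, "sfad_config"))
  ok <- vapply(trajs, function(tr) {
    n <- nrow(tr$points)
    n >= cfg$min_frames ||
      (cfg$exempt_initial && !is.null(video_start) &&
         tr$start_frame == video_start)
  }, logical(1))
  list(valid = trajs[ok], excluded = trajs[!ok])
}

#' Per-step displacements of one trajectory
#'
#' Euclidean distances between successive trajectory points. With
#' `consecutive_only` (the default), pairs of points more than one frame apart
#' — i.e. across a tracking gap — are dropped rather than spuriously summed
#' into one long step.
#'
#' @param traj One trajectory (list with a `points` data frame).
#' @param cfg An [sfad_config()].
#' @return A data frame `frame, dist` with one row per counted step; `frame`
#'   is the later frame of the pair.
#' @export
step_displacements <- function(traj, cfg = sfad_config()) {
  pts <- traj$points
  n <- nrow(pts)
  if (n < 2L) return(data.frame(frame = integer(), dist = numeric()))
  gap <- diff(pts$frame)
  d <- sqrt(diff(pts$Sx)^2 + diff(pts$Sy)^2)
  keep <- if (cfg$consecutive_only) gap == 1L else rep(TRUE, n - 1L)
  data.frame(frame = pts$frame[-1][keep], dist = d[keep])
}

#' Single-frame average displacement (SFAD)
#'
#' The activity statistic: the average per-frame displacement of tracked
#' individuals over a video. In the default `pooled_steps` mode,
#' `L = sum of all counted step lengths / number of counted steps`, pooling
#' every valid trajectory — a frame-count-weighted mean, so long trajectories
#' carry proportionally more weight. In `per_track_mean` mode each trajectory
#' contributes its own mean step length with equal weight. With no counted
#' steps, `L = 0` and the report is flagged empty.
#'
#' @param trajs Validity-filtered trajectories (see [filter_valid()]).
#' @param cfg An [sfad_config()].
#' @param video_id Optional identifier carried into the report.
#' @param excluded_tracks Optional ids of excluded trajectories, for the
#'   report.
#' @return An object of class `sfad_report`: `video_id`, `L` (pixels/frame),
#'   `n_valid_tracks`, `n_steps`, `total_path`, `excluded_tracks`, `mode`,
#'   `empty`.
#' @examples
#' tr <- list(track_id = 1,
#'            points = data.frame(frame = 0:3, Sx = c(0, 3, 6, 9),
#'                                Sy = c(0, 4, 8, 12)))
#' sfad(list(tr), sfad_config(min_frames = 2))$L   # 5 (3-4-5 steps)
#' @export
sfad <- function(trajs, cfg = sfad_config(), video_id = NA,
                 excluded_tracks = integer(0)) {
  stopifnot(inherits(cfg, "sfad_config"))
  steps <- lapply(trajs, step_displacements, cfg = cfg)
  per_len <- vapply(steps, function(s) sum(s$dist), numeric(1))
  per_n <- vapply(steps, nrow, integer(1))
  n_steps <- sum(per_n)
  total <- sum(per_len)
  L <- if (n_steps == 0L) {
    0
  } else if (cfg$denominator_mode == "pooled_steps") {
    total / n_steps
  } else {
    mean(per_len[per_n > 0] / per_n[per_n > 0])
  }
  structure(list(
    video_id = video_id, L = L, n_valid_tracks = length(trajs),
    n_steps = n_steps, total_path = total,
    excluded_tracks = excluded_tracks, mode = cfg$denominator_mode,
    empty = n_steps == 0L
  ), class = "sfad_report")
}

#' @export
print.sfad_report <- function(x, ...) {
  cat(sprintf("<sfad_report%s> SFAD = %.4f px/frame (%s)\n",
              if (is.na(x$video_id)) "" else paste0(" ", x$video_id),
              x$L, x$mode))
  cat(sprintf("  %d valid trajectories, %d counted steps, %d excluded%s\n",
              x$n_valid_tracks, x$n_steps, length(x$excluded_tracks),
              if (x$empty) " [no valid steps]" else ""))
  invisible(x)
}

#' SFAD straight from a centroid table
#'
#' Convenience wrapper: [build_trajectories()], [filter_valid()], [sfad()].
#'
#' @inheritParams build_trajectories
#' @inheritParams sfad
#' @param cfg An [sfad_config()].
#' @param video_start 0-based first frame of the video (defaults to the
#'   earliest frame present), used by the initial-trajectory exemption.
#' @return An `sfad_report`.
#' @export
compute_sfad <- function(centroids, cfg = sfad_config(), video_id = NA,
                         video_start = NULL) {
  trajs <- build_trajectories(centroids)
  if (is.null(video_start) && length(trajs)) {
    video_start <- min(vapply(trajs, function(t) t$start_frame, numeric(1)))
  }
  fl <- filter_valid(trajs, cfg, video_start)
  sfad(fl$valid, cfg, video_id = video_id,
       excluded_tracks = vapply(fl$excluded, function(t) t$track_id,
                                numeric(1)))
}

#' Aggregate per-video SFAD values by group
#'
#' Plain arithmetic mean of the member values within each group (e.g. mean
#' over a cage's videos, or over the three cages of a photoperiod group), with
#' the conventional 3-decimal reporting rounding alongside the unrounded mean.
#'
#' @param reports Data frame holding one row per member with the SFAD values
#'   and grouping columns.
#' @param by Name of the grouping column.
#' @param value Name of the value column (default `"L"`).
#' @return A data frame `group, n, mean_L, mean_L_3dp`.
#' @examples
#' df <- data.frame(photoperiod = rep("16L:8D", 3), L = c(0.856, 0.953, 0.909))
#' aggregate_sfad(df, by = "photoperiod")$mean_L_3dp   # 0.906
#' @export
aggregate_sfad <- function(reports, by, value = "L") {
  if (!by %in% names(reports)) stopf("unknown group key '%s'", by)
  if (!value %in% names(reports)) stopf("unknown value column '%s'", value)
  groups <- split(reports[[value]], reports[[by]])
  out <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean_L = vapply(groups, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$mean_L_3dp <- round(out$mean_L, 3)
  rownames(out) <- NULL
  out
}

#' Relative change of a value against a reference, in percent
#'
#' Sign convention: positive for a reduction (`value < reference`), so
#' "activity reduced by 1.99%" corresponds to `relative_change(0.983, 1.003)`.
#'
#' @param value,reference Numeric scalars; `reference` must be nonzero.
#' @return `(reference - value) / reference * 100`.
#' @export
relative_change <- function(value, reference) {
  if (!is_num1(value) || !is_num1(reference)) stopf("inputs must be numeric")
  if (reference == 0) stopf("reference must be nonzero")
  (reference - value) / reference * 100
}

# canonical rearing-age stages (days, closed ranges)
.age_stages <- data.frame(
  label = c("6-13", "14-19", "20-25", "26-31"),
  lo = c(6, 14, 20, 26),
  hi = c(13, 19, 25, 31),
  stringsAsFactors = FALSE
)

#' Assign ages (days) to rearing-age stages
#'
#' The four closed stages are 6–13, 14–19, 20–25 and 26–31 days. Ages outside
#' all stages map to `NA` with a warning.
#'
#' @param age_days Numeric vector of ages in days.
#' @return A factor with levels `"6-13", "14-19", "20-25", "26-31"`.
#' @export
age_stage <- function(age_days) {
  idx <- vapply(age_days, function(a) {
    k <- which(a >= .age_stages$lo & a <= .age_stages$hi)
    if (length(k) == 1L) k else NA_integer_
  }, integer(1))
  if (anyNA(idx)) {
    warnf("%d age(s) outside the 6-31 day range excluded", sum(is.na(idx)))
  }
  factor(.age_stages$label[idx], levels = .age_stages$label)
}

#' Mean SFAD per rearing-age stage
#'
#' @param reports Data frame with an SFAD value column and an age column.
#' @param age_col Name of the age-in-days column.
#' @param value Name of the value column.
#' @return A data frame `group, n, mean_L, mean_L_3dp`, one row per non-empty
#'   stage.
#' @export
stage_summary <- function(reports, age_col = "age_days", value = "L") {
  if (!age_col %in% names(reports)) stopf("unknown group key '%s'", age_col)
  reports$stage <- age_stage(reports[[age_col]])
  reports <- reports[!is.na(reports$stage), , drop = FALSE]
  aggregate_sfad(reports, by = "stage", value = value)
}
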