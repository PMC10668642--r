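#' Read a MOTChallenge-format text file
#'
#' One comma-separated line per object:
#' `frame,id,bb_left,bb_top,bb_width,bb_height,conf,x,y,z`. Frames are 1-based
#' on disk and mapped to 0-based in memory; the trailing `x,y,z` world
#' coordinates (−1 in this 2-D setting) are dropped.
#'
#' @param path File path.
#' @return A data frame `frame, id, x, y, w, h, conf`.
#' @export
read_mot <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(frame = integer(), id = integer(), x = numeric(),
                      y = numeric(), w = numeric(), h = numeric(),
                      conf = numeric()))
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 10L)
  if (length(bad)) {
    stopf("malformed MOT line %d in '%s': expected 10 fields, found %d",
          bad[1], path, nf[bad[1]])
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 10L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stopf("malformed MOT line %d in '%s': non-numeric field", bad, path)
  }
  data.frame(frame = as.integer(m[, 1]) - 1L, id = as.integer(m[, 2]),
             x = m[, 3], y = m[, 4], w = m[, 5], h = m[, 6], conf = m[, 7])
}

#' Write detections or tracklets in MOTChallenge format
#'
#' The inverse of [read_mot()]: 0-based in-memory frames become 1-based on
#' disk, coordinates and confidences are written with 6 decimal places, and
#' missing ids (detection files) are written as −1, as are the world
#' coordinates.
#'
#' @param df Data frame with columns `frame, x, y, w, h, conf` and optionally
#'   `id`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mot <- function(df, path) {
  id <- if ("id" %in% names(df)) df$id else rep(-1L, nrow(df))
  id[is.na(id)] <- -1L
  lines <- sprintf("%d,%d,%.6f,%.6f,%.6f,%.6f,%.6f,-1,-1,-1",
                   df$frame + 1L, id, df$x, df$y, df$w, df$h, df$conf)
  writeLines(lines, path)
  invisible(path)
}

#' Export instance masks as PNG files with an index
#'
#' Writes each agent's mask for the requested frames as an 8-bit PNG
#' (`<frame>_<agent>.png`, background 0, foreground 255, 1-based frame in the
#' filename) plus an `index.csv` mapping mask ids to files and box origins.
#'
#' @param truth A `scene_truth` from [simulate_scene()].
#' @param dir Output directory (created if needed).
#' @param frames 0-based frames to export (default: all — beware of volume on
#'   long clips).
#' @return The index data frame, invisibly.
#' @export
write_masks <- function(truth, dir, frames = NULL) {
  stopifnot(inherits(truth, "scene_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  frames <- frames %||% unique(truth$poses$frame)
  store <- mask_store_scene(truth)
  rows <- list()
  for (f in frames) {
    p <- truth$poses[truth$poses$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(p))) {
      id <- sprintf("%d_%d", f, p$agent_id[i])
      msk <- get_mask(store, id)
      file <- sprintf("%d_%d.png", f + 1L, p$agent_id[i])
      png::writePNG(msk$grid + 0, file.path(dir, file))  # needs real-valued
      rows[[length(rows) + 1L]] <- data.frame(
        mask_id = id, file = file, frame = f, agent = p$agent_id[i],
        Zx = msk$origin[1], Zy = msk$origin[2], stringsAsFactors = FALSE)
    }
  }
  index <- do.call(rbind, rows)
  utils::write.csv(index, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(index)
}

#' Mask store backed by a PNG directory
#'
#' Reads the `index.csv` written by [write_masks()] and serves
#' [instance_mask()] objects from the PNG rasters (binarized at 0.5).
#'
#' @param dir Directory containing `index.csv` and the mask PNGs.
#' @return A mask store for [get_mask()].
#' @export
read_mask_dir <- function(dir) {
  idx_path <- file.path(dir, "index.csv")
  if (!file.exists(idx_path)) stopf("no index.csv in '%s'", dir)
  index <- utils::read.csv(idx_path, stringsAsFactors = FALSE)
  structure(list(dir = dir, index = index),
            class = c("mask_store_dir", "mask_store"))
}

#' @export
get_mask.mask_store_dir <- function(store, id) {
  row <- store$index[store$index$mask_id == id, , drop = FALSE]
  if (nrow(row) != 1L) return(NULL)
  path <- file.path(store$dir, row$file)
  if (!file.exists(path)) stopf("mask file missing: '%s'", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  binarize_mask(img, 0.5, origin = c(row$Zx, row$Zy))
}

#' Total recording hours of a video inventory
#'
#' @param n_segments Number of recorded clips.
#' @param minutes_each Clip length in minutes.
#' @return Hours of footage: `n_segments * minutes_each / 60`.
#' @examples
#' inventory_hours(2658, 6)   # 265.8
#' @export
inventory_hours <- function(n_segments, minutes_each) {
  if (!is_num1(n_segments) || n_segments < 0 ||
      !is_num1(minutes_each) || minutes_each < 0) {
    stopf("inputs must be nonnegative")
  }
  n_segments * minutes_each / 60
}

#' Convert a frame count to seconds
#'
#' @param frames Number of frames.
#' @param fps Frame rate; must be positive.
#' @return `frames / fps` seconds (60 frames at 30 fps = 2 s, the
#'   trajectory-validity horizon).
#' @export
frames_to_seconds <- function(frames, fps) {
  if (!is_num1(fps) || fps <= 0) stopf("fps must be positive")
  frames / fps
}
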