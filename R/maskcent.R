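#' Construct an instance mask
#'
#' A binary raster anchored in the image frame. The grid is stored with rows
#' along y and columns along x; `origin = (Zx, Zy)` gives the image
#' coordinates of the grid's first pixel (0-based). Pixel `(ix, iy)` of the
#' grid therefore sits at image coordinates `(Zx + ix, Zy + iy)`.
#'
#' @param grid Matrix of 0/1 (or logical) values.
#' @param origin Length-2 numeric, image coordinates of the grid origin.
#' @return An object of class `instance_mask`.
#' @export
instance_mask <- function(grid, origin = c(0, 0)) {
  grid <- if (is.logical(grid)) {
    matrix(as.integer(grid), nrow = nrow(grid))
  } else {
    grid
  }
  if (!is.matrix(grid) || !all(grid %in% c(0L, 1L))) {
    stopf("mask grid must be a binary (0/1) matrix")
  }
  if (!is.numeric(origin) || length(origin) != 2L) {
    stopf("origin must be length-2 numeric")
  }
  structure(list(grid = grid, origin = as.numeric(origin)),
            class = "instance_mask")
}

#' Threshold a soft mask into a binary instance mask
#'
#' @param soft_mask Numeric matrix with values in `[0, 1]`.
#' @param threshold Values at or above this become foreground (default 0.5).
#' @param origin Image coordinates of the grid origin.
#' @return An [instance_mask()].
#' @export
binarize_mask <- function(soft_mask, threshold = 0.5, origin = c(0, 0)) {
  if (!is.matrix(soft_mask) || any(soft_mask < 0) || any(soft_mask > 1)) {
    stopf("soft_mask must be a matrix with values in [0, 1]")
  }
  instance_mask(soft_mask >= threshold, origin)
}

#' Raw image moments of a binary mask
#'
#' Zeroth and first moments over the foreground: `M00 = sum(mask)` (area in
#' pixels), `M10 = sum of x indices`, `M01 = sum of y indices`, with `x`, `y`
#' the 0-based column/row indices of the foreground pixels.
#'
#' @param mask An [instance_mask()] or a plain 0/1 matrix.
#' @return A list of class `image_moments` with `M00`, `M10`, `M01`.
#' @examples
#' m <- matrix(0L, 8, 8); m[8, 4] <- 1L   # single pixel at (x = 3, y = 7)
#' mask_moments(m)                        # M00 = 1, M10 = 3, M01 = 7
#' @export
mask_moments <- function(mask) {
  g <- if (inherits(mask, "instance_mask")) mask$grid else mask
  if (!is.matrix(g) || !all(g %in% c(0L, 1L))) {
    stopf("mask must be binary")
  }
  xs <- 0:(ncol(g) - 1)
  ys <- 0:(nrow(g) - 1)
  structure(list(
    M00 = sum(g),
    M10 = sum(colSums(g) * xs),
    M01 = sum(rowSums(g) * ys)
  ), class = "image_moments")
}

#' Centroid from image moments
#'
#' `Cx = M10 / M00`, `Cy = M01 / M00`, in the mask's local (box) frame. An
#' empty mask (`M00 = 0`) has no centroid and raises a condition of class
#' `flocktrack_degenerate_mask`, which [extract_centroid()] catches to fall
#' back to the box centre.
#'
#' @param m An `image_moments` object (or anything coercible via
#'   [mask_moments()]).
#' @return Numeric `(Cx, Cy)`.
#' @export
moments_centroid <- function(m) {
  if (!inherits(m, "image_moments")) m <- mask_moments(m)
  if (m$M00 == 0) {
    stop(structure(
      class = c("flocktrack_degenerate_mask", "error", "condition"),
      list(message = "degenerate mask: zero area (M00 = 0)", call = NULL)
    ))
  }
  c(Cx = m$M10 / m$M00, Cy = m$M01 / m$M00)
}

#' Transfer a box-local centroid to image coordinates
#'
#' `Sx = Zx + Cx`, `Sy = Zy + Cy`, where `(Zx, Zy)` is the image-frame anchor
#' of the mask's bounding box.
#'
#' @param local Numeric `(Cx, Cy)` in the box frame.
#' @param box_origin Numeric `(Zx, Zy)`.
#' @return Numeric `(Sx, Sy)`.
#' @examples
#' centroid_to_image(c(2.5, 3.5), c(12, 40))  # (14.5, 43.5)
#' @export
centroid_to_image <- function(local, box_origin) {
  c(Sx = box_origin[1] + local[1], Sy = box_origin[2] + local[2])
}

#' Representative point of one detection
#'
#' If the detection carries an instance mask with nonzero area, the point is
#' the mask-moment centroid transferred to image coordinates. Otherwise
#' (missing mask or zero-area mask) the detection's box centre is used and the
#' source is flagged `box_center_fallback` with a warning. The fallback centre
#' is expressed in the same pixel-index convention as the moment centroid
#' (mean foreground index of a filled box, `x + (w - 1) / 2`), so trajectories
#' do not jump by half a pixel when a mask drops out.
#'
#' @param det A one-row detection (list or data frame row) with `x, y, w, h`
#'   and optionally `mask_id`.
#' @param store Optional mask store ([mask_store_scene()] or
#'   [read_mask_dir()]) resolving `mask_id` to an [instance_mask()].
#' @param quiet Suppress the fallback warning (used by [centroid_table()],
#'   which reports fallbacks in aggregate).
#' @return A list of class `centroid_point`: `local`, `global`, `source`.
#' @export
extract_centroid <- function(det, store = NULL, quiet = FALSE) {
  mask <- NULL
  if (!is.null(store) && !is.null(det$mask_id) && !is.na(det$mask_id)) {
    mask <- get_mask(store, det$mask_id)
  }
  if (!is.null(mask)) {
    m <- mask_moments(mask)
    if (m$M00 > 0) {
      local <- moments_centroid(m)
      return(structure(list(
        local = unname(local),
        global = unname(centroid_to_image(local, mask$origin)),
        source = "mask_moment"
      ), class = "centroid_point"))
    }
  }
  if (!quiet) warnf("no usable mask; falling back to box centre")
  structure(list(
    local = c((det$w - 1) / 2, (det$h - 1) / 2),
    global = c(det$x + (det$w - 1) / 2, det$y + (det$h - 1) / 2),
    source = "box_center_fallback"
  ), class = "centroid_point")
}

#' Centroid table for a set of tracklets
#'
#' Resolves every tracked observation to a representative point and returns
#' the per-frame centroid table consumed by the activity statistics. Fallbacks
#' to the box centre are counted and reported once.
#'
#' @param tracks A `flock_tracks` object from [track_flock()], or a data frame
#'   with columns `frame, id, x, y, w, h, mask_id`.
#' @param store Optional mask store.
#' @return A data frame `frame, track_id, Sx, Sy, source`.
#' @export
centroid_table <- function(tracks, store = NULL) {
  df <- if (inherits(tracks, "flock_tracks")) as.data.frame(tracks) else tracks
  n <- nrow(df)
  Sx <- numeric(n); Sy <- numeric(n); src <- character(n)
  for (i in seq_len(n)) {
    cp <- extract_centroid(df[i, , drop = FALSE], store, quiet = TRUE)
    Sx[i] <- cp$global[1]; Sy[i] <- cp$global[2]; src[i] <- cp$source
  }
  nfall <- sum(src == "box_center_fallback")
  if (nfall > 0) {
    warnf("%d of %d observations fell back to the box centre (no mask)",
          nfall, n)
  }
  data.frame(frame = df$frame, track_id = df$id, Sx = Sx, Sy = Sy,
             source = src, stringsAsFactors = FALSE)
}

## ---- mask stores ----

#' Lazy mask store backed by simulator ground truth
#'
#' Re-renders an agent's elliptical instance mask on demand from the truth
#' poses, keyed by `"<frame>_<agent_id>"` (0-based frame) — the `mask_id`
#' stamped on true detections by [corrupt_detections()]. Avoids materialising
#' every mask of a long clip in memory.
#'
#' @param truth A `scene_truth` object from [simulate_scene()].
#' @return A mask store for [get_mask()].
#' @export
mask_store_scene <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  structure(list(truth = truth), class = c("mask_store_scene", "mask_store"))
}

#' In-memory mask store
#'
#' Wraps a named list of [instance_mask()] objects, keyed by mask id. Handy
#' for small scenes and for feeding externally produced masks into
#' [centroid_table()].
#'
#' @param masks Named list of `instance_mask` objects.
#' @return A mask store for [get_mask()].
#' @export
mask_store_list <- function(masks) {
  stopifnot(is.list(masks), !is.null(names(masks)),
            all(vapply(masks, inherits, logical(1), "instance_mask")))
  structure(list(masks = masks), class = c("mask_store_list", "mask_store"))
}

#' @export
get_mask.mask_store_list <- function(store, id) {
  store$masks[[id]]
}

#' Fetch an instance mask from a store
#'
#' @param store A mask store.
#' @param id Mask identifier (`"<frame>_<index>"`).
#' @return An [instance_mask()], or `NULL` if the id is unknown.
#' @export
get_mask <- function(store, id) UseMethod("get_mask")

#' @export
get_mask.mask_store_scene <- function(store, id) {
  parts <- strsplit(id, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2L) return(NULL)
  f <- as.integer(parts[1]); a <- as.integer(parts[2])
  p <- store$truth$poses
  row <- p[p$frame == f & p$agent_id == a, , drop = FALSE]
  if (nrow(row) != 1L) return(NULL)
  ab <- store$truth$config$body_semi_axes
  r <- .render_ellipse(row$x, row$y, row$heading, ab[1], ab[2])
  instance_mask(r$grid, r$origin)
}
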