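#' Match one frame of tracker output against ground truth
#'
#' CLEAR-style correspondence: matches carried over from the previous frame
#' are kept whenever the pair still overlaps at `IoU >= iou_thr` (sticky
#' correspondences); the remaining objects are matched one-to-one by optimal
#' assignment on IoU, subject to the same gate. Unmatched ground-truth objects
#' count as misses, unmatched hypotheses as false positives, and a ground-truth
#' object whose matched hypothesis ID differs from its most recent prior match
#' — including re-acquisition after a gap — counts as an identity switch.
#'
#' @param gt,hyp Data frames for one frame: `id, x, y, w, h`. IDs must be
#'   unique within each frame.
#' @param prev_corr Correspondence memory: named numeric vector mapping
#'   ground-truth id (as name) to the hypothesis id it was last matched with.
#'   Pass the `corr` of the previous frame's result; `NULL` to start.
#' @param iou_thr Minimum IoU for a valid correspondence (default 0.5).
#' @return A list of class `frame_eval`: `m` (misses), `f` (false positives),
#'   `s` (switches), `g` (ground-truth count), and the updated `corr` memory.
#' @export
match_frame <- function(gt, hyp, prev_corr = NULL, iou_thr = 0.5) {
  if (anyDuplicated(gt$id)) stopf("duplicate ground-truth ids within a frame")
  if (anyDuplicated(hyp$id)) stopf("duplicate hypothesis ids within a frame")
  corr <- prev_corr %||% stats::setNames(numeric(0), character(0))
  ng <- nrow(gt); nh <- nrow(hyp)
  iou <- iou_matrix(gt[, c("x", "y", "w", "h"), drop = FALSE],
                    hyp[, c("x", "y", "w", "h"), drop = FALSE])

  matched_g <- rep(FALSE, ng); matched_h <- rep(FALSE, nh)
  match_of <- rep(NA_integer_, ng)   # hyp row matched to each gt row

  # 1. sticky correspondences
  if (ng && nh) {
    for (i in seq_len(ng)) {
      prev <- corr[as.character(gt$id[i])]
      if (is.na(prev)) next
      j <- match(prev, hyp$id)
      if (!is.na(j) && !matched_h[j] && iou[i, j] >= iou_thr) {
        matched_g[i] <- TRUE; matched_h[j] <- TRUE; match_of[i] <- j
      }
    }
  }

  # 2. optimal assignment for the remainder, gated at iou_thr
  gi <- which(!matched_g); hj <- which(!matched_h)
  if (length(gi) && length(hj)) {
    cost <- 1 - iou[gi, hj, drop = FALSE]
    cost[iou[gi, hj, drop = FALSE] < iou_thr] <- Inf
    res <- associate(cost, gate = 1 - iou_thr)
    if (nrow(res$matches)) {
      for (k in seq_len(nrow(res$matches))) {
        i <- gi[res$matches[k, "row"]]; j <- hj[res$matches[k, "col"]]
        matched_g[i] <- TRUE; matched_h[j] <- TRUE; match_of[i] <- j
      }
    }
  }

  # 3. count errors and update the memory
  s <- 0L
  for (i in which(matched_g)) {
    key <- as.character(gt$id[i])
    new_id <- hyp$id[match_of[i]]
    if (!is.na(corr[key]) && length(corr[key]) && !is.null(corr[key])) {
      if (corr[key] != new_id) s <- s + 1L
    }
    corr[key] <- new_id
  }
  structure(list(m = sum(!matched_g), f = sum(!matched_h), s = s, g = ng,
                 corr = corr),
            class = "frame_eval")
}

#' Multi-object tracking accuracy from per-frame error counts
#'
#' `R_MOTA = 1 - (sum m + sum f + sum s) / sum g`: one minus the ratio of
#' total misses, false positives and identity switches to the total number of
#' ground-truth objects. At most 1; can be negative when errors outnumber
#' objects.
#'
#' @param frames A data frame with columns `m, f, s, g` (one row per frame) or
#'   a list of `frame_eval` objects.
#' @return An object of class `mota_report`: `R_MOTA`, `totals`, `frames`.
#' @examples
#' mota(data.frame(m = 1, f = 1, s = 1, g = 20))$R_MOTA   # 0.85
#' @export
mota <- function(frames) {
  if (!is.data.frame(frames)) {
    frames <- do.call(rbind, lapply(frames, function(fe) {
      data.frame(m = fe$m, f = fe$f, s = fe$s, g = fe$g)
    }))
  }
  totals <- c(m = sum(frames$m), f = sum(frames$f), s = sum(frames$s),
              g = sum(frames$g))
  if (totals["g"] <= 0) stopf("no ground-truth objects (sum g = 0)")
  structure(list(
    R_MOTA = unname(1 - (totals["m"] + totals["f"] + totals["s"]) /
                      totals["g"]),
    totals = totals, frames = frames
  ), class = "mota_report")
}

#' @export
print.mota_report <- function(x, ...) {
  cat(sprintf("<mota_report> MOTA = %.4f\n", x$R_MOTA))
  cat(sprintf("  misses %d, false positives %d, switches %d, objects %d\n",
              x$totals["m"], x$totals["f"], x$totals["s"], x$totals["g"]))
  invisible(x)
}

#' Evaluate a tracking result against ground truth
#'
#' Runs [match_frame()] over every frame present in the ground truth (frames
#' with no hypotheses count all their objects as misses) and folds the counts
#' into [mota()].
#'
#' @param gt,hyp Data frames across frames: `frame, id, x, y, w, h`.
#' @param iou_thr Correspondence gate (default 0.5).
#' @return A `mota_report` whose `frames` element carries the per-frame
#'   `frame, m, f, s, g` trace.
#' @export
mota_eval <- function(gt, hyp, iou_thr = 0.5) {
  frames <- sort(unique(c(gt$frame, hyp$frame)))
  gt_by <- split(gt, factor(gt$frame, levels = frames))
  hyp_by <- split(hyp, factor(hyp$frame, levels = frames))
  corr <- NULL
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fe <- match_frame(gt_by[[k]], hyp_by[[k]], corr, iou_thr)
    corr <- fe$corr
    rows[[k]] <- data.frame(frame = frames[k], m = fe$m, f = fe$f, s = fe$s,
                            g = fe$g)
  }
  mota(do.call(rbind, rows))
}

#' Difference of two unit-interval metrics in percentage points
#'
#' @param a,b Metric values in `[0, 1]` (e.g. two MOTA scores).
#' @return `(a - b) * 100`.
#' @examples
#' diff_points(0.851, 0.769)   # 8.2 points
#' @export
diff_points <- function(a, b) (a - b) * 100

#' Relative gain of one value over another, in percent
#'
#' @param a New value.
#' @param b Baseline; must be positive.
#' @return `(a - b) / b * 100`.
#' @examples
#' relative_gain(0.979, 0.965)   # ~1.45 %
#' @export
relative_gain <- function(a, b) {
  if (!is_num1(a) || !is_num1(b)) stopf("inputs must be numeric scalars")
  if (b <= 0) stopf("baseline must be positive")
  (a - b) / b * 100
}

#' FLOPs of a partial convolution
#'
#' A partial convolution applies a regular convolution to only `cp` of the
#' feature map's channels, costing `h * w * k^2 * cp^2` floating-point
#' operations for an `h x w` map and `k x k` kernel.
#'
#' @param h,w Feature-map height and width.
#' @param k Kernel size.
#' @param cp Number of channels convolved.
#' @return The FLOP count.
#' @examples
#' pconv_flops(10, 10, 3, 16)   # 230400
#' @export
pconv_flops <- function(h, w, k, cp) {
  for (v in list(h, w, k, cp)) {
    if (!is_count(v, 1L)) stopf("h, w, k, cp must be positive integers")
  }
  h * w * k^2 * cp^2
}

#' FLOPs ratio of a partial convolution to a regular convolution
#'
#' With the regular convolution costing `h * w * k^2 * c^2` over all `c`
#' channels, the ratio is `(cp / c)^2` — independent of the map size and
#' kernel. Convolving a quarter of the channels (`cp = c / 4`) costs 1/16 of
#' the full convolution.
#'
#' @param c Total channel count.
#' @param cp Channels convolved (default `c / 4`).
#' @return `(cp / c)^2`.
#' @export
pconv_ratio <- function(c, cp = c / 4) {
  if (!is_num1(c) || !is_num1(cp) || c <= 0 || cp <= 0) {
    stopf("c and cp must be positive")
  }
  if (cp > c) stopf("cp cannot exceed c")
  (cp / c)^2
}
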