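det_row <- function(frame, x, y, w = 10, h = 10, conf = 0.9) {
  data.frame(frame = frame, x = x, y = y, w = w, h = h, conf = conf,
             mask_id = NA_character_, stringsAsFactors = FALSE)
}

test_that("confidence partition uses half-open tier boundaries", {
  cfg <- tracker_config()
  conf_dets <- function(confs) {
    do.call(rbind, lapply(confs, function(cf) det_row(0, 0, 0, conf = cf)))
  }
  p <- partition_by_confidence(conf_dets(c(0.05, 0.30, 0.50)), cfg)
  expect_equal(p$discarded$conf, 0.05)
  expect_equal(p$low$conf, 0.30)
  expect_equal(p$high$conf, 0.50)

  pe <- partition_by_confidence(conf_dets(c(0.1, 0.45)), cfg)
  expect_equal(pe$low$conf, 0.1)
  expect_equal(pe$high$conf, 0.45)

  empty <- partition_by_confidence(det_row(0, 0, 0)[0, ], cfg)
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))

  # the three tiers are disjoint and cover the input
  set.seed(1)
  many <- conf_dets(runif(50))
  pm <- partition_by_confidence(many, cfg)
  expect_equal(sum(vapply(pm, nrow, integer(1))), 50L)
})

test_that("IoU matches hand geometry and is symmetric", {
  a <- c(0, 0, 10, 10)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, c(20, 20, 5, 5)), 0)
  b <- c(5, 0, 10, 10)
  expect_equal(box_iou(a, b), 1 / 3)
  expect_equal(box_iou(b, a), 1 / 3)
  # edge-touching boxes do not overlap under the half-open convention
  expect_equal(box_iou(a, c(10, 0, 10, 10)), 0)
})

test_that("Kalman prediction follows the constant-velocity model", {
  cfg <- tracker_config()
  tr <- flocktrack:::.new_track(1L, det_row(0, 100, 50, 20, 12), cfg)

  still <- kalman_predict(tr, cfg)
  expect_equal(still$mean[1:4], tr$mean[1:4])

  tr2 <- tr
  tr2$mean[5:6] <- c(3, -1)
  moved <- kalman_predict(tr2, cfg)
  expect_equal(moved$mean[1], tr2$mean[1] + 3)
  expect_equal(moved$mean[2], tr2$mean[2] - 1)

  expect_gt(sum(diag(still$cov)), sum(diag(tr$cov)))
})

test_that("Kalman update matches the scalar closed form on each component", {
  cfg <- tracker_config()
  tr <- flocktrack:::.new_track(1L, det_row(0, 100, 50, 20, 12), cfg)
  tr <- kalman_predict(tr, cfg)
  det <- det_row(1, 108, 47, 20, 12)
  z <- c(108 + 10, 47 + 6, 20, 12)

  # with diagonal P over the measured block and diagonal R, the filter
  # decouples into scalar problems: x' = x + p/(p+r) (z - x)
  s <- pmax(tr$mean[3:4], 1)
  r <- (cfg$measurement_noise * c(s[1], s[2], s[1], s[2]))^2
  p <- diag(tr$cov)[1:4]
  expected <- tr$mean[1:4] + p / (p + r) * (z - tr$mean[1:4])

  up <- kalman_update(tr, det, cfg)
  expect_equal(up$mean[1:4], expected, tolerance = 1e-10)
  expect_equal(up$frames_since_update, 0L)
  expect_equal(up$hits, tr$hits + 1L)

  # posterior lies between prior and measurement, component-wise
  lo <- pmin(tr$mean[1:4], z); hi <- pmax(tr$mean[1:4], z)
  expect_true(all(up$mean[1:4] >= lo - 1e-9 & up$mean[1:4] <= hi + 1e-9))

  # measurement equal to the prediction leaves the position unchanged
  same <- kalman_update(tr, det_row(1, tr$mean[1] - tr$mean[3] / 2,
                                    tr$mean[2] - tr$mean[4] / 2,
                                    tr$mean[3], tr$mean[4]), cfg)
  expect_equal(same$mean[1:4], tr$mean[1:4], tolerance = 1e-10)
})

test_that("near-zero measurement noise pulls the posterior onto the measurement", {
  cfg <- tracker_config(measurement_noise = 1e-8)
  tr <- flocktrack:::.new_track(1L, det_row(0, 100, 50, 20, 12), cfg)
  tr$cov <- diag(8)  # non-degenerate prior
  up <- kalman_update(tr, det_row(1, 130, 70, 24, 16), cfg)
  expect_equal(up$mean[1:4], c(130 + 12, 70 + 8, 24, 16), tolerance = 1e-4)
})

test_that("gated assignment is optimal and reports the unmatched", {
  one <- associate(matrix(0.2, 1, 1), gate = 0.5)
  expect_equal(one$matches, cbind(row = 1L, col = 1L))

  diag3 <- matrix(0.9, 3, 3); diag(diag3) <- 0.05
  res <- associate(diag3, gate = 0.5)
  expect_equal(res$matches[, "col"][order(res$matches[, "row"])], 1:3)

  # optimality vs brute force, square and rectangular, sizes up to 6
  set.seed(42)
  for (rep_i in 1:25) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    cost <- matrix(sample(seq(0.1, 0.9, by = 0.1), n * m, replace = TRUE), n, m)
    res <- associate(cost, gate = 1)
    k <- min(n, m)
    expect_equal(nrow(res$matches), k)
    # pad to square and compare against exhaustive enumeration
    big <- 1e6
    sq <- matrix(big, max(n, m), max(n, m))
    sq[1:n, 1:m] <- cost
    got <- sum(cost[res$matches])
    expect_equal(got, bf_assignment_cost(sq) - (max(n, m) - k) * big,
                 tolerance = 1e-6)
  }

  # gate removal happens after the optimal assignment
  res <- associate(matrix(c(0.9, 0.2), 1, 2), gate = 0.5)
  expect_equal(nrow(res$matches), 1L)
  expect_equal(unname(res$matches[1, "col"]), 2L)
})

test_that("a coasting track survives 30 missed frames but not 31", {
  cfg <- tracker_config()
  base <- function(gap) {
    pre <- do.call(rbind, lapply(0:4, function(f) det_row(f, 100, 100)))
    post <- det_row(5 + gap, 100, 100)
    track_flock(rbind(pre, post), cfg, n_frames = 6 + gap)
  }
  same_id <- base(29)   # 29 empty frames: within the retention window
  expect_equal(length(same_id$tracklets), 1L)
  expect_equal(nrow(same_id$tracklets[[1]]$obs), 6L)

  # 31 consecutive misses delete the track; the reappearing box cannot be
  # re-associated and (being a lone unconfirmed detection) never confirms
  gone <- base(31)
  expect_equal(length(gone$tracklets), 1L)
  expect_equal(nrow(gone$tracklets[[1]]$obs), 5L)
})

test_that("a reappearing detection after deletion receives a fresh ID", {
  cfg <- tracker_config()
  pre <- do.call(rbind, lapply(0:4, function(f) det_row(f, 100, 100)))
  post <- do.call(rbind, lapply(37:40, function(f) det_row(f, 100, 100)))
  tr <- track_flock(rbind(pre, post), cfg, n_frames = 41)
  expect_equal(length(tr$tracklets), 2L)
  ids <- vapply(tr$tracklets, function(t) t$track_id, numeric(1))
  expect_equal(length(unique(ids)), 2L)   # never reused
})

test_that("a noiseless single agent yields one full-length tracklet", {
  cfg <- scene_config(arena_width = 400, arena_height = 300, n_agents = 1,
                      n_frames = 100, body_semi_axes = c(12, 7), seed = 8)
  sc <- simulate_scene(cfg, noise_config(miss_prob = 0, fp_rate = 0,
                                         box_jitter_sd = 0, seed = 9))
  tr <- track_flock(sc$detections, tracker_config(), n_frames = 100)
  expect_equal(length(tr$tracklets), 1L)
  expect_equal(nrow(tr$tracklets[[1]]$obs), 100L)
  expect_equal(tr$tracklets[[1]]$obs$frame, 0:99)
})

test_that("detections below the discard threshold produce no tracks", {
  dets <- do.call(rbind, lapply(0:20, function(f) det_row(f, 50, 50,
                                                          conf = 0.05)))
  tr <- track_flock(dets, tracker_config(), n_frames = 21)
  expect_equal(length(tr$tracklets), 0L)
})

test_that("tracker output is a subset of its input detections", {
  ws <- well_separated_scene(80, miss_prob = 0.1, fp_rate = 0.5,
                             box_jitter_sd = 1)
  dets <- ws$scene$detections
  tr <- track_flock(dets, tracker_config(), n_frames = 80)
  out <- as.data.frame(tr)
  key <- function(d) paste(d$frame, round(d$x, 9), round(d$y, 9),
                           round(d$conf, 9))
  expect_true(all(key(out) %in% key(dets)))
  # no two concurrent observations share an ID
  expect_false(any(duplicated(out[, c("frame", "id")])))
})

test_that("more detector misses never means fewer tracking misses", {
  misses_at <- function(mp) {
    ws <- well_separated_scene(120, miss_prob = mp)
    tr <- track_flock(ws$scene$detections, tracker_config(), n_frames = 120)
    mo <- mota_eval(truth_as_gt(ws$scene$truth), as.data.frame(tr))
    unname(mo$totals["m"])
  }
  m <- vapply(c(0, 0.05, 0.2, 0.5), misses_at, numeric(1))
  expect_true(all(diff(m) >= 0))
})

test_that("per-frame detection lists must have increasing frames", {
  d1 <- det_row(0, 0, 0); d2 <- det_row(1, 0, 0)
  expect_error(track_flock(list(d2, d1), tracker_config()), "increasing")
  ok <- track_flock(list(d1, d2), tracker_config())
  expect_s3_class(ok, "flock_tracks")
})
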