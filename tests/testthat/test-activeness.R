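cent_rows <- function(track_id, frames, x, y) {
  data.frame(frame = frames, track_id = track_id, Sx = x, Sy = y)
}

test_that("trajectories assemble per identity, insensitive to row order", {
  tab <- cent_rows(7L, 0:4, (0:4) * 2, 0)
  tr <- build_trajectories(tab)
  expect_length(tr, 1L)
  expect_equal(tr[[1]]$track_id, 7)
  expect_equal(nrow(tr[[1]]$points), 5L)
  expect_equal(tr[[1]]$start_frame, 0)
  expect_equal(tr[[1]]$end_frame, 4)

  expect_length(build_trajectories(tab[0, ]), 0L)

  set.seed(2)
  two <- rbind(tab, cent_rows(3L, 10:12, 0, 1:3))
  shuffled <- two[sample(nrow(two)), ]
  expect_equal(build_trajectories(shuffled), build_trajectories(two))

  dup <- rbind(tab, tab[1, ])
  expect_error(build_trajectories(dup), "duplicate")
})

test_that("the 60-frame validity rule excludes 59 and keeps 60", {
  cfg <- sfad_config()
  t59 <- build_trajectories(cent_rows(1L, 100 + 0:58, 0, 0))
  t60 <- build_trajectories(cent_rows(2L, 100 + 0:59, 0, 0))
  fl <- filter_valid(c(t59, t60), cfg)
  expect_equal(vapply(fl$excluded, function(t) t$track_id, numeric(1)), 1)
  expect_equal(vapply(fl$valid, function(t) t$track_id, numeric(1)), 2)

  all_long <- filter_valid(t60, cfg)
  expect_length(all_long$excluded, 0L)

  # a short trajectory that starts at the first video frame is exempt
  t_initial <- build_trajectories(cent_rows(3L, 0:9, 0, 0))
  expect_length(filter_valid(t_initial, cfg, video_start = 0)$valid, 1L)
  expect_length(filter_valid(t_initial, cfg, video_start = NULL)$valid, 0L)
  strict <- sfad_config(exempt_initial = FALSE)
  expect_length(filter_valid(t_initial, strict, video_start = 0)$valid, 0L)
})

test_that("step displacements are Euclidean and respect tracking gaps", {
  cfg <- sfad_config(min_frames = 2)
  still <- build_trajectories(cent_rows(1L, 0:9, 5, 5))[[1]]
  expect_true(all(step_displacements(still, cfg)$dist == 0))

  moving <- build_trajectories(cent_rows(1L, 0:9, (0:9) * 3, (0:9) * 4))[[1]]
  expect_equal(step_displacements(moving, cfg)$dist, rep(5, 9))

  # 6-point toy with a 5-frame gap between the 3rd and 4th points
  gap <- build_trajectories(
    cent_rows(1L, c(0, 1, 2, 7, 8, 9), c(0, 1, 2, 10, 11, 12), 0))[[1]]
  d_consec <- step_displacements(gap, cfg)
  expect_equal(nrow(d_consec), 4L)            # gap pair dropped
  expect_equal(d_consec$dist, rep(1, 4))
  cfg_all <- sfad_config(min_frames = 2, consecutive_only = FALSE)
  d_all <- step_displacements(gap, cfg_all)
  expect_equal(nrow(d_all), 5L)               # one 8 px step across the gap
  expect_equal(sort(d_all$dist), c(1, 1, 1, 1, 8))
})

test_that("the two SFAD denominators agree and disagree as designed", {
  cfg <- sfad_config(min_frames = 2)
  # constant 5 px/frame: both modes give 5
  one <- build_trajectories(cent_rows(1L, 0:10, (0:10) * 3, (0:10) * 4))
  expect_equal(sfad(one, cfg)$L, 5)
  cfg_pt <- sfad_config(min_frames = 2, denominator_mode = "per_track_mean")
  expect_equal(sfad(one, cfg_pt)$L, 5)

  # A: 100 steps of 1 px; B: 50 steps of 3 px
  a <- build_trajectories(cent_rows(1L, 0:100, 0:100, 0))
  b <- build_trajectories(cent_rows(2L, 0:50, (0:50) * 3, 0))
  both <- c(a, b)
  expect_equal(sfad(both, cfg)$L, 250 / 150)
  expect_equal(sfad(both, cfg_pt)$L, 2)

  # no steps at all: flagged empty with L = 0
  lone <- build_trajectories(cent_rows(1L, 0, 0, 0))
  rep0 <- sfad(lone, cfg)
  expect_equal(rep0$L, 0)
  expect_true(rep0$empty)
})

test_that("SFAD is translation-invariant and scales linearly", {
  set.seed(13)
  frames <- 0:199
  tab <- rbind(
    cent_rows(1L, frames, cumsum(rnorm(200)), cumsum(rnorm(200))),
    cent_rows(2L, frames, cumsum(rnorm(200)), cumsum(rnorm(200)))
  )
  cfg <- sfad_config()
  base <- compute_sfad(tab, cfg)$L
  shifted <- tab; shifted$Sx <- shifted$Sx + 123; shifted$Sy <- shifted$Sy - 45
  expect_equal(compute_sfad(shifted, cfg)$L, base)
  scaled <- tab; scaled$Sx <- scaled$Sx * 2.5; scaled$Sy <- scaled$Sy * 2.5
  expect_equal(compute_sfad(scaled, cfg)$L, 2.5 * base)
  expect_gte(base, 0)
})

test_that("pooled SFAD equals total path length over total steps", {
  set.seed(14)
  tab <- do.call(rbind, lapply(1:4, function(id) {
    n <- sample(60:120, 1)
    cent_rows(id, seq_len(n) - 1, cumsum(rnorm(n)), cumsum(rnorm(n)))
  }))
  cfg <- sfad_config()
  rep <- compute_sfad(tab, cfg)
  # independent conservation identity
  path <- 0; steps <- 0
  for (id in 1:4) {
    d <- tab[tab$track_id == id, ]
    path <- path + sum(sqrt(diff(d$Sx)^2 + diff(d$Sy)^2))
    steps <- steps + nrow(d) - 1
  }
  expect_equal(rep$L, path / steps)
  expect_equal(rep$n_steps, steps)
})

test_that("splitting a trajectory shifts pooled SFAD by exactly the lost step", {
  set.seed(15)
  n <- 300
  tab <- cent_rows(1L, 0:(n - 1), cumsum(rnorm(n)), cumsum(rnorm(n)))
  cfg <- sfad_config()
  full <- compute_sfad(tab, cfg)
  # split into two >= 60-frame pieces under different IDs
  split_tab <- tab
  split_tab$track_id[151:n] <- 2L
  parted <- compute_sfad(split_tab, cfg, video_start = 0)
  d_lost <- sqrt((tab$Sx[151] - tab$Sx[150])^2 + (tab$Sy[151] - tab$Sy[150])^2)
  n_steps <- n - 1
  expect_equal(abs(parted$L - full$L),
               abs(full$L - d_lost) / (n_steps - 1))
})

test_that("group aggregation reproduces the published photoperiod means", {
  df <- data.frame(
    photoperiod = rep(c("24L:0D", "16L:8D", "12L:12D"), each = 3),
    L = c(0.975, 1.041, 0.995, 0.856, 0.953, 0.909, 1.002, 0.863, 1.085)
  )
  agg <- aggregate_sfad(df, by = "photoperiod")
  expect_equal(agg$mean_L_3dp[agg$group == "16L:8D"], 0.906)
  expect_equal(agg$mean_L_3dp[agg$group == "12L:12D"], 0.983)
  expect_equal(agg$mean_L[agg$group == "16L:8D"],
               mean(c(0.856, 0.953, 0.909)))

  single <- aggregate_sfad(data.frame(g = "a", L = 0.5), by = "g")
  expect_equal(single$mean_L, 0.5)

  expect_error(aggregate_sfad(df, by = "cage"), "unknown group key")
})

test_that("relative change uses the reduction sign convention", {
  expect_equal(round(relative_change(0.983, 1.003), 2), 1.99)
  expect_equal(relative_change(1, 1), 0)
  expect_equal(relative_change(0.5, 1), 50)
  expect_error(relative_change(1, 0), "nonzero")
})

test_that("age-stage binning follows the four closed ranges", {
  expect_equal(as.character(age_stage(c(6, 13, 14, 19, 20, 25, 26, 31))),
               c("6-13", "6-13", "14-19", "14-19", "20-25", "20-25",
                 "26-31", "26-31"))
  expect_warning(out <- age_stage(c(5, 10, 35)), "outside")
  expect_true(is.na(out[1]) && is.na(out[3]))

  df <- data.frame(age_days = 6:31, L = 1)
  expect_equal(nrow(stage_summary(df)), 4L)   # all four stages populated
})
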