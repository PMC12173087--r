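test_that("target orientations are uniform on the circle and reproducible", {
  set.seed(1); a <- draw_target_orientation(5)
  set.seed(1); b <- draw_target_orientation(5)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a < 360))
  # Rayleigh test of uniformity: 2 n Rbar^2 ~ chi^2(2) under uniformity
  set.seed(2)
  x <- draw_target_orientation(1e5)
  stat <- 2 * length(x) * circ_mean(x)$rbar^2
  expect_gt(pchisq(stat, df = 2, lower.tail = FALSE), 0.01)
})

test_that("flanker gaps sit at 90-degree intervals around a noisy first gap", {
  set.seed(5)
  noise <- rnorm(1, 0, 45)
  set.seed(5)
  gaps <- assign_flanker_gaps(0, sd_deg = 45)
  expect_equal(gaps[1], wrap_360(noise))
  expect_equal(gaps, wrap_360(gaps[1] + c(0, 90, 180, 270)))
  # pairwise circular differences between consecutive sorted gaps are all 90
  expect_equal(diff(sort(gaps)), rep(90, 3), tolerance = 1e-12)
  # dispersion of the first gap about the target orientation is the configured SD
  set.seed(6)
  g1 <- replicate(1e4, assign_flanker_gaps(180, 45)[1])
  expect_equal(circ_sd(g1), 45, tolerance = 45 * 0.02)
  expect_equal(circ_mean(g1)$mean_deg, 180, tolerance = 2)
})

test_that("distance trajectory sweeps linearly and clamps at the range", {
  cfg <- default_cfg()
  d_inc <- distance_trajectory(cfg, "increasing")
  i10 <- which.min(abs((seq_along(d_inc) - 1) / cfg$sample_rate_hz - 10))
  expect_equal(d_inc[i10], 1.3, tolerance = 1e-6)
  d_dec <- distance_trajectory(cfg, "decreasing")
  # 5 - 0.13 * 40 = -0.2 unclamped; the trace must hold at 0
  expect_equal(d_dec[length(d_dec)], 0)
  expect_true(all(d_dec >= 0 & d_dec <= 5))
  cfg0 <- paradigm_config(distance_speed_deg_s = 0,
                          jump_distances_deg = numeric(0))
  expect_equal(unique(distance_trajectory(cfg0, "increasing")), 0)
  expect_error(distance_trajectory(cfg, "increasing", start_distance_deg = 5),
               "must start")
})

test_that("jump times are the first crossings of the preselected distances", {
  cfg <- default_cfg()
  expect_equal(jump_times_for_trend(cfg, "increasing"),
               c(0.31, 0.35, 1.35, 2.20, 3.37) / 0.13)
  expect_equal(jump_times_for_trend(cfg, "decreasing"),
               (5 - c(3.37, 2.20, 1.35, 0.35, 0.31)) / 0.13)
  expect_length(jump_times_for_trend(cfg, "increasing"), 5)
  expect_length(jump_times_for_trend(cfg, "decreasing"), 5)
})

test_that("continuous trials have the documented frame and jump structure", {
  cfg <- default_cfg()
  tr <- generate_continuous_trial(cfg, "flanked", "increasing", seed = 9)
  expect_equal(nrow(tr), 5760)
  expect_equal(sum(tr$is_jump), 5)
  expect_true(all(tr$target_ori_deg >= 0 & tr$target_ori_deg < 360))
  expect_true(all(tr$distance_deg >= 0 & tr$distance_deg <= 5))
  # between jumps the unwrapped step is exactly +/- 0.5 deg/frame
  step <- wrap_180(diff(tr$target_ori_deg))
  inside <- !tr$is_jump[-1]
  expect_true(all(abs(abs(step[inside]) - 0.5) < 1e-9))
  # 72 deg of rotation accumulates over any jump-free second (144 frame
  # advances; step[j] is the advance from frame j to j+1)
  i0 <- which(tr$time_s >= 5)[1]
  expect_false(any(tr$is_jump[(i0 + 1):(i0 + cfg$sample_rate_hz)]))
  expect_equal(sum(abs(step[i0:(i0 + cfg$sample_rate_hz - 1)])), 72,
               tolerance = 1e-9)
  # flanker channels stay at fixed 90-degree offsets from gap 1
  for (k in 2:4) {
    off <- wrap_180(tr[[paste0("flank", k, "_ori_deg")]] - tr$flank1_ori_deg)
    expect_equal(unique(round(wrap_360(off))), (k - 1) * 90)
  }
})

test_that("isolated trials carry the matched jump schedule but no flankers", {
  cfg <- default_cfg()
  fl <- generate_continuous_trial(cfg, "flanked", "decreasing", seed = 4)
  iso <- generate_continuous_trial(cfg, "isolated", "decreasing", seed = 4)
  expect_identical(which(iso$is_jump), which(fl$is_jump))
  expect_true(all(is.na(iso$flank1_ori_deg)))
  expect_identical(iso$distance_deg, fl$distance_deg)
})

test_that("trial generation is deterministic in the seed", {
  cfg <- default_cfg()
  expect_identical(generate_continuous_trial(cfg, "flanked", "increasing", seed = 77),
                   generate_continuous_trial(cfg, "flanked", "increasing", seed = 77))
  cfg0 <- paradigm_config(rotation_speed_deg_s = 0, jump_distances_deg = numeric(0))
  tr0 <- generate_continuous_trial(cfg0, "flanked", "increasing", seed = 1)
  expect_equal(length(unique(tr0$target_ori_deg)), 1)
})

test_that("block and trial-based schedules have the paradigm's composition", {
  cfg <- default_cfg()
  sched <- build_block_schedule(cfg, seed = 10)
  expect_equal(nrow(sched), 12)
  expect_equal(sum(sched$condition == "flanked"), 8)
  expect_equal(sum(sched$condition == "isolated"), 4)
  expect_equal(sum(sched$condition == "flanked" & sched$trend == "increasing"), 4)
  expect_equal(sum(sched$condition == "isolated" & sched$trend == "decreasing"), 2)
  expect_identical(sched, build_block_schedule(cfg, seed = 10))

  tb <- build_trial_based_schedule(cfg, seed = 10)
  expect_equal(nrow(tb), 200)
  counts <- table(tb$distance_deg, useNA = "ifany")
  expect_true(all(counts == 25))
  cfg1 <- paradigm_config(trial_based_reps = 1)
  expect_equal(nrow(build_trial_based_schedule(cfg1, seed = 1)), 8)
})

test_that("log-spaced helper reproduces the geometric construction", {
  expect_equal(log_spaced_jump_distances(),
               exp(seq(log(0.8), log(5.8), length.out = 5)) - 0.8)
  expect_equal(log_spaced_jump_distances()[1], 0)
  expect_equal(log_spaced_jump_distances()[5], 5)
})

test_that("config validation rejects out-of-range and unknown values", {
  expect_error(paradigm_config(rotation_speed_deg_s = -1), "rotation_speed")
  expect_error(paradigm_config(jump_distances_deg = c(2, 1)), "ascending")
  expect_error(paradigm_config(jump_distances_deg = c(1, 6)), "inside")
  expect_error(paradigm_config(n_flanked_per_block = 7), "even")
  expect_error(observer_config(baseline_noise_sd_deg = -2), "baseline_noise")
})
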