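test_that("noise SD follows the hinge in distance", {
  obs <- observer_config(baseline_noise_sd_deg = 10,
                         crowding_slope_deg_per_deg = 8,
                         crowding_extent_deg = 5)
  expect_equal(perceived_noise_sd(5, obs), 10)
  expect_equal(perceived_noise_sd(Inf, obs), 10)
  expect_equal(perceived_noise_sd(0, obs), 50)
  d <- seq(0, 8, by = 0.1)
  expect_true(all(diff(perceived_noise_sd(d, obs)) <= 0))
})

test_that("an ideal observer reproduces the stimulus exactly", {
  cfg <- paradigm_config(jump_distances_deg = numeric(0))
  stim <- generate_continuous_trial(cfg, "flanked", "increasing", seed = 3)
  tr <- simulate_tracking_response(stim, ideal_observer(), seed = 4)
  expect_equal(tr$response_ori_deg, stim$target_ori_deg, tolerance = 1e-9)
  expect_equal(cosine_similarity(tr$target_ori_deg, tr$response_ori_deg), 1)
})

test_that("a jump imposes the reassignment error, held through the latency", {
  cfg <- default_cfg()
  stim <- generate_continuous_trial(cfg, "isolated", "increasing", seed = 8)
  obs <- ideal_observer(motor_latency_ms = 280,
                        recovery_rate_isolated_per_s = 3.5)
  tr <- simulate_tracking_response(stim, obs, seed = 5)
  err <- abs(report_error(tr$target_ori_deg, tr$response_ori_deg))
  j <- which(stim$is_jump)[1]
  L <- round(0.280 * cfg$sample_rate_hz)
  # no error before the first jump; the jump error appears instantly and is
  # held at its initial magnitude for at least the motor latency
  expect_true(all(err[seq_len(j - 1)] < 1e-9))
  expect_gt(err[j], 1)
  expect_equal(err[j:(j + L - 1)], rep(err[j], L), tolerance = 1e-9)
})

test_that("steady-state report error has the configured noise SD", {
  cfg <- default_cfg()
  obs <- observer_config(crowding_extent_deg = 5, baseline_noise_sd_deg = 10)
  stim <- generate_continuous_trial(cfg, "isolated", "increasing", seed = 12)
  tr <- simulate_tracking_response(stim, obs, seed = 13)
  err <- report_error(tr$target_ori_deg, tr$response_ori_deg)
  # exclude reacquisition periods: keep frames > 3 s after any jump
  jf <- which(stim$is_jump)
  keep <- rep(TRUE, nrow(tr))
  for (j in jf) keep[j:min(j + 3 * cfg$sample_rate_hz, nrow(tr))] <- FALSE
  expect_equal(circ_sd(err[keep]), 10, tolerance = 10 * 0.1)
})

test_that("flankers impair tracking for any observer with a positive slope", {
  cfg <- default_cfg()
  set.seed(31)
  for (k in 1:5) {
    obs <- observer_config(
      baseline_noise_sd_deg = runif(1, 5, 15),
      crowding_slope_deg_per_deg = runif(1, 4, 12),
      crowding_extent_deg = runif(1, 2, 5),
      seed = k
    )
    stim_fl <- generate_continuous_trial(cfg, "flanked", "increasing", seed = 100 + k)
    stim_iso <- generate_continuous_trial(cfg, "isolated", "increasing", seed = 100 + k)
    cs_fl <- with(simulate_tracking_response(stim_fl, obs, seed = 200 + k),
                  cosine_similarity(target_ori_deg, response_ori_deg))
    cs_iso <- with(simulate_tracking_response(stim_iso, obs, seed = 200 + k),
                   cosine_similarity(target_ori_deg, response_ori_deg))
    expect_lt(cs_fl, cs_iso)
  }
})

test_that("trial-based reports follow the hinge-linked Von Mises model", {
  obs <- observer_config()
  expect_identical(simulate_trial_based_response(90, 2, obs, seed = 5),
                   simulate_trial_based_response(90, 2, obs, seed = 5))
  # zero noise: the degenerate Von Mises returns the target orientation
  obs0 <- observer_config(baseline_noise_sd_deg = 0, crowding_slope_deg_per_deg = 0)
  expect_equal(simulate_trial_based_response(123.4, 1, obs0, seed = 1), 123.4)
  # at an uncrowded distance the report SD matches the baseline noise SD
  obs <- observer_config(baseline_noise_sd_deg = 10, crowding_extent_deg = 5)
  reps <- vapply(seq_len(1e4), function(i) {
    simulate_trial_based_response(0, 5, obs, seed = i)
  }, numeric(1))
  expect_equal(circ_sd(report_error(0, reps)), 10, tolerance = 10 * 0.03)
})

test_that("datasets have the paradigm's trial counts and are reproducible", {
  ds <- tiny_dataset(seed = 42)
  expect_equal(nrow(ds$continuous), 2 * 1 * 12 * 5760)
  expect_equal(nrow(ds$trial_based), 2 * 200)
  expect_equal(length(unique(ds$continuous$trial)), 12)
  expect_true(all(ds$continuous$response_ori_deg >= 0 &
                    ds$continuous$response_ori_deg < 360))
  expect_true(all(ds$trial_based$report_ori_deg >= 0 &
                    ds$trial_based$report_ori_deg < 360))
  ds2 <- tiny_dataset(seed = 42)
  expect_identical(ds$continuous, ds2$continuous)
  expect_identical(ds$trial_based, ds2$trial_based)
})
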