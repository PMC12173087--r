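test_that("report error wraps to [-180, 180) with the -180 tie convention", {
  expect_equal(report_error(350, 10), 20)
  expect_equal(report_error(10, 10), 0)
  expect_equal(report_error(0, 180), -180)
  expect_equal(report_error(10, 350), -20)
  # antisymmetry away from the boundary
  set.seed(9)
  a <- runif(200, 0, 360); b <- runif(200, 0, 360)
  away <- abs(abs(wrap_180(b - a)) - 180) > 1e-6
  expect_equal(report_error(a, b)[away], -report_error(b, a)[away])
})

make_error_trials <- function(values_list, trends, dist_axis) {
  purrr::imap_dfr(values_list, function(v, i) {
    tibble::tibble(
      trial = i, frame = seq_along(v), time_s = (seq_along(v) - 1) / 144,
      trend = trends[i],
      distance_deg = if (trends[i] == "decreasing") rev(dist_axis) else dist_axis,
      abs_error_deg = v
    )
  })
}

test_that("flip-and-average aligns trends on a common increasing axis", {
  dist <- seq(0, 5, length.out = 10)
  up <- 1:10
  trials <- make_error_trials(list(up, rev(up)), c("increasing", "decreasing"), dist)
  avg <- flip_and_average(trials)
  # the decreasing trial is the exact time-mirror: the average equals the
  # increasing series
  expect_equal(avg$abs_error_deg, up)
  expect_equal(avg$distance_deg, dist)
  expect_equal(avg$n_trials, rep(2L, 10))

  zeros <- make_error_trials(list(rep(0, 10), rep(0, 10)),
                             c("increasing", "increasing"), dist)
  expect_equal(flip_and_average(zeros)$abs_error_deg, rep(0, 10))

  # frame-wise mean matches a brute-force recomputation for many trials
  set.seed(4)
  vals <- purrr::map(1:8, ~ runif(10, 0, 40))
  trends <- rep(c("increasing", "decreasing"), 4)
  trials8 <- make_error_trials(vals, trends, dist)
  avg8 <- flip_and_average(trials8)
  brute <- rowMeans(sapply(seq_along(vals), function(i) {
    if (trends[i] == "decreasing") rev(vals[[i]]) else vals[[i]]
  }))
  expect_equal(avg8$abs_error_deg, brute)

  # scaling all inputs scales the average (commutes with frame-wise scaling)
  trials8_scaled <- dplyr::mutate(trials8, abs_error_deg = abs_error_deg * 3)
  expect_equal(flip_and_average(trials8_scaled)$abs_error_deg,
               3 * avg8$abs_error_deg)

  bad <- dplyr::bind_rows(trials, dplyr::mutate(trials[1:5, ], trial = 99))
  expect_error(flip_and_average(bad), "unequal lengths")
})

test_that("artifact cleaning marks spike segments from the isolated trial", {
  base <- rep(c(-2, 2), 55)[1:100]
  e <- base
  e[40:49] <- 30
  iso <- tibble::tibble(signed_error_deg = e, abs_error_deg = abs(e))
  fl <- tibble::tibble(signed_error_deg = rev(e), abs_error_deg = abs(rev(e)))
  out <- clean_artifacts(iso, fl)
  # hand-computed thresholds: the spike exceeds 2 SD; the surrounding +/-2
  # baseline is below mean + 1 SD, so exactly the spike frames are marked
  expect_gt(30, out$thresholds$peak)
  expect_lt(2, out$thresholds$extend)
  expect_equal(which(out$mask), 40:49)
  expect_identical(out$isolated$deleted, out$flanked$deleted)
  expect_equal(out$thresholds$fraction_removed, 0.1)
})

test_that("cleaning is a no-op for constant series", {
  iso <- tibble::tibble(signed_error_deg = rep(5, 50), abs_error_deg = rep(5, 50))
  out <- clean_artifacts(iso, iso)
  expect_false(any(out$mask))
  iso0 <- tibble::tibble(signed_error_deg = rep(0, 50), abs_error_deg = rep(0, 50))
  expect_false(any(clean_artifacts(iso0, iso0)$mask))
  expect_error(clean_artifacts(iso, iso[1:10, ]), "lengths differ")
})

test_that("post-jump windows align to jumps and respect boundaries", {
  err <- rep(7, 1000)
  w <- extract_post_jump_windows(err, jump_indices = 100, window_samples = 300,
                                 skip_samples = 0, dt_s = 1 / 144)
  expect_equal(dim(w$window_matrix), c(1, 300))
  expect_equal(unname(w$mean_error), rep(7, 300))
  expect_equal(w$time_s[1], 0)
  expect_equal(w$time_s[300], 299 / 144)

  wskip <- extract_post_jump_windows(err, 100, skip_samples = 40)
  expect_equal(ncol(wskip$window_matrix), 260)
  expect_equal(wskip$time_s[1], 40 / 144)

  # a second jump truncates the first window; no value is read across it
  err2 <- c(rep(1, 99), rep(2, 100), rep(3, 801))
  w2 <- extract_post_jump_windows(err2, c(100, 200), window_samples = 300,
                                  skip_samples = 0)
  expect_equal(w2$window_matrix[1, 1:100], rep(2, 100))
  expect_true(all(is.na(w2$window_matrix[1, 101:300])))
  expect_equal(w2$window_matrix[2, ], rep(3, 300))

  expect_error(extract_post_jump_windows(err, integer(0)), "empty jump list")
})
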