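test_that("cosine similarity reduces to the mean cosine of the report error", {
  set.seed(13)
  s <- runif(1000, 0, 360)
  r <- wrap_360(s + rnorm(1000, 0, 30))
  # oracle: direct evaluation of the reduced form
  expect_equal(cosine_similarity(s, r),
               mean(cos(pi / 180 * (s - r))), tolerance = 1e-12)
  expect_equal(cosine_similarity(s, s), 1, tolerance = 1e-12)
  expect_equal(cosine_similarity(s, wrap_360(s + 180)), -1, tolerance = 1e-12)
  # invariant under a common rotation of both series
  expect_equal(cosine_similarity(wrap_360(s + 57), wrap_360(r + 57)),
               cosine_similarity(s, r), tolerance = 1e-12)
  expect_error(cosine_similarity(numeric(0), numeric(0)), "empty")
  expect_error(cosine_similarity(1:3, 1:4), "lengths differ")
})

test_that("error-vs-distance regression matches closed-form OLS", {
  x <- c(0, 1, 2, 3, 5)
  y <- c(11, 9.5, 7, 6, 2.2)
  fit <- fit_error_vs_distance(y, x)
  # oracle: normal equations computed directly
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)

  exact <- fit_error_vs_distance(3 - 2 * x, x)
  expect_equal(exact$slope, -2, tolerance = 1e-12)
  expect_equal(exact$intercept, 3, tolerance = 1e-12)
  expect_error(fit_error_vs_distance(y, rep(1, 5)), "distinct")
})

test_that("regression-intersection extent reproduces the hand-computed crossing", {
  fl <- fit_error_vs_distance(12 - 2 * c(0, 1, 2), c(0, 1, 2), "flanked")
  iso <- fit_error_vs_distance(rep(2, 3) + c(0, 1e-13, -1e-13), c(0, 1, 2), "isolated")
  ext <- crowding_extent_continuous(fl, iso, max_distance_deg = 5)
  expect_equal(ext$extent_deg, 5, tolerance = 1e-6)
  # clipping retains the raw crossing
  ext2 <- crowding_extent_continuous(
    structure(list(slope = -2, intercept = 20, condition = "flanked", n = 2), class = "line_fit"),
    structure(list(slope = 0, intercept = 2, condition = "isolated", n = 2), class = "line_fit"),
    max_distance_deg = 5)
  expect_equal(ext2$extent_deg, 5)
  expect_equal(ext2$raw_extent_deg, 9)
  expect_error(crowding_extent_continuous(fl, fl, 5), "parallel")
})

test_that("perceptual error handles degenerate and sampled input", {
  expect_equal(perceptual_error_vonmises(rep(0, 10))$circular_sd_deg, 0)
  expect_error(perceptual_error_vonmises(c(1, 2)), "at least 5")
  set.seed(17)
  pe <- perceptual_error_vonmises(wrap_180(rvonmises(1e4, 0, 4)))
  expect_equal(pe$kappa, 4, tolerance = 4 * 0.05)
})

test_that("trial-based extent: intersection and hinge on exact profiles", {
  # sigma(d) = 30 - 5 d against baseline 5 crosses at d = 5
  d <- c(0, 0.5, 1, 2, 3)
  prof <- tibble::tibble(distance_deg = d, circular_sd_deg = 30 - 5 * d)
  ext <- crowding_extent_trial_based(prof, baseline_sd_deg = 5, max_distance_deg = 5)
  expect_equal(ext$extent_deg, 5, tolerance = 1e-9)

  flat <- tibble::tibble(distance_deg = d, circular_sd_deg = rep(5, 5))
  ext0 <- crowding_extent_trial_based(flat, 5, 5)
  expect_equal(ext0$extent_deg, 0)
  expect_match(ext0$status, "degenerate")

  rising <- tibble::tibble(distance_deg = d, circular_sd_deg = 5 + d)
  extr <- crowding_extent_trial_based(rising, 5, 5)
  expect_equal(extr$extent_deg, 5)
  expect_match(extr$status, "no crossing")

  # hinged fit recovers an interior hinge exactly from noiseless data
  dd <- seq(0, 5, by = 0.5)
  hing <- tibble::tibble(distance_deg = dd,
                         circular_sd_deg = 10 + 6 * pmax(0, 2.5 - dd))
  exth <- crowding_extent_trial_based(hing, 10, 5, method = "hinged")
  expect_equal(exth$extent_deg, 2.5, tolerance = 0.02)
  expect_error(crowding_extent_trial_based(prof[1:2, ], 5, 5), ">= 3")
})

test_that("exponential decay fit recovers noiseless parameters", {
  t <- (0:299) / 144
  y <- 40 * exp(-3 * t) + 8
  fit <- fit_exponential_decay(y, 1 / 144)
  expect_equal(fit$a_deg, 40, tolerance = 1e-6)
  expect_equal(fit$b_per_s, 3, tolerance = 1e-6)
  expect_equal(fit$c_deg, 8, tolerance = 1e-6)
  expect_lt(fit$rmse_deg, 1e-6)

  const <- fit_exponential_decay(rep(12, 50), 1 / 144)
  expect_equal(const$a_deg, 0)
  expect_equal(const$c_deg, 12)
  expect_error(fit_exponential_decay(y[1:5], 1 / 144), ">= 10")
})

test_that("decay fit time origin only rescales the initial amplitude", {
  t <- (40:299) / 144
  y <- 40 * exp(-3 * t) + 8
  fit <- fit_exponential_decay(y, 1 / 144, motor_corrected = TRUE,
                               start_time_s = 40 / 144)
  expect_equal(fit$b_per_s, 3, tolerance = 1e-6)
  expect_equal(fit$a_deg, 40, tolerance = 1e-5)
  expect_true(fit$motor_corrected)
})

test_that("sequential t-tests find the recovery column", {
  dt <- 1 / 144
  mk <- function(M) {
    structure(list(window_matrix = M, mean_error = colMeans(M),
                   time_s = (seq_len(ncol(M)) - 1) * dt, dt_s = dt,
                   skip_samples = 0L), class = "post_jump_windows")
  }
  # constant windows: already indistinguishable at the first column
  rt0 <- recovery_time(mk(matrix(5, nrow = 10, ncol = 120)))
  expect_equal(rt0$recovery_ms, 0)
  expect_true(rt0$recovered)

  # step high -> low at column 60 with tiny noise: recovery at ~ column 60
  set.seed(23)
  M <- cbind(matrix(50 + rnorm(10 * 59, 0, 0.1), 10, 59),
             matrix(rnorm(10 * 61, 0, 0.1), 10, 61))
  rt <- recovery_time(mk(M))
  expect_equal(rt$recovery_ms, (60 - 1) / 144 * 1000, tolerance = 2 * dt * 1000)

  # never non-significant: columns alternate tightly around 10 and 90, so
  # every column mean differs from the mixed baseline pool (mean 50)
  Mr <- matrix(rep(c(10, 90), length.out = 120), nrow = 10, ncol = 120,
               byrow = TRUE) + rnorm(1200, 0, 0.1)
  rtr <- recovery_time(mk(Mr))
  expect_false(rtr$recovered)
  expect_equal(rtr$recovery_ms, 119 / 144 * 1000, tolerance = 1e-6)
  expect_error(recovery_time(mk(Mr[1, , drop = FALSE])), ">= 2 jumps")
})

test_that("noise profile recovers a distance-dependent SD", {
  set.seed(29)
  n <- 20000
  d <- runif(n, 0, 5)
  dir <- sample(c(-1L, 1L), n, replace = TRUE)
  sd_true <- 10 + 6 * pmax(0, 3 - d)
  errors <- tibble::tibble(
    signed_error_deg = wrap_180(dir * 15 + rnorm(n, 0, sd_true)),
    distance_deg = d, direction = dir
  )
  prof <- noise_profile(errors, bin_width_deg = 0.5)
  # the direction-split circular SD removes the +/-15 offset
  hi <- prof$circular_sd_deg[prof$distance_deg > 3.5]
  expect_equal(mean(hi), 10, tolerance = 0.6)
  lo <- prof$circular_sd_deg[prof$distance_deg < 0.5]
  expect_equal(mean(lo), 10 + 6 * (3 - 0.25), tolerance = 1.5)
})
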