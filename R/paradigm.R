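# Stimulus-side generation: orientation/distance trajectories, jump
# scheduling, flanker gap assignment, and block / trial-based schedules.

# Deterministic sub-seed derivation: mixes integer labels into a seed
# < 2^31 so every trial has an independently reproducible RNG stream.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Draw a target gap orientation
#'
#' Uniform on the full circle.
#'
#' @param n Number of draws.
#' @return Orientations in degrees, `[0, 360)`.
#' @export
draw_target_orientation <- function(n = 1) {
  stats::runif(n, 0, 360) %% 360
}

#' Assign the four flanker gap orientations
#'
#' The first gap is drawn from a normal distribution centred on the target
#' gap orientation (wrapped to the circle); the remaining three sit at 90 deg
#' intervals from it.
#'
#' @param target_orientation_deg Target gap orientation, deg.
#' @param sd_deg SD of the centring normal, deg.
#' @return Numeric vector of 4 orientations in `[0, 360)`.
#' @export
assign_flanker_gaps <- function(target_orientation_deg, sd_deg = 45) {
  gap1 <- wrap_360(target_orientation_deg + stats::rnorm(1, 0, sd_deg))
  wrap_360(gap1 + c(0, 90, 180, 270))
}

#' Target-flanker distance trajectory
#'
#' Linear sweep at the configured speed, clamped to the distance range.
#' Increasing trials start at the minimum distance, decreasing trials at the
#' maximum.
#'
#' @param config A [paradigm_config()].
#' @param trend `"increasing"` or `"decreasing"`.
#' @param start_distance_deg Optional start distance; must equal the range
#'   end consistent with `trend`.
#' @return Numeric vector of per-frame distances (deg), length
#'   `round(sample_rate_hz * trial_duration_s)`.
#' @export
distance_trajectory <- function(config, trend = c("increasing", "decreasing"),
                                start_distance_deg = NULL) {
  trend <- match.arg(trend)
  expected_start <- if (trend == "increasing") config$distance_min_deg else config$distance_max_deg
  if (!is.null(start_distance_deg) && start_distance_deg != expected_start) {
    stop(sprintf("distance_trajectory: %s trials must start at %g deg (got %g)",
                 trend, expected_start, start_distance_deg), call. = FALSE)
  }
  n <- round(config$sample_rate_hz * config$trial_duration_s)
  t <- (seq_len(n) - 1) / config$sample_rate_hz
  sgn <- if (trend == "increasing") 1 else -1
  d <- expected_start + sgn * config$distance_speed_deg_s * t
  pmin(pmax(d, config$distance_min_deg), config$distance_max_deg)
}

#' Jump times implied by a distance trend
#'
#' One jump per configured jump distance, at the first time the (unclamped)
#' sweep reaches it. Increasing trials hit the distances in ascending order,
#' decreasing trials in descending order.
#'
#' @inheritParams distance_trajectory
#' @return Numeric vector of jump times in seconds, sorted ascending,
#'   strictly inside `(0, trial_duration_s)`.
#' @export
jump_times_for_trend <- function(config, trend = c("increasing", "decreasing")) {
  trend <- match.arg(trend)
  if (config$distance_speed_deg_s == 0 || !length(config$jump_distances_deg)) {
    return(numeric(0))
  }
  jd <- config$jump_distances_deg
  tt <- if (trend == "increasing") {
    (jd - config$distance_min_deg) / config$distance_speed_deg_s
  } else {
    (config$distance_max_deg - jd) / config$distance_speed_deg_s
  }
  tt <- sort(tt)
  tt[tt > 0 & tt < config$trial_duration_s]
}

jump_frames_for_trend <- function(config, trend) {
  # first frame whose timestamp is at or past the crossing time
  tt <- jump_times_for_trend(config, trend)
  unique(pmin(as.integer(ceiling(tt * config$sample_rate_hz - 1e-9)) + 1L,
              round(config$sample_rate_hz * config$trial_duration_s)))
}

#' Generate one continuous-paradigm stimulus trial
#'
#' The target (and, when flanked, the four flanker gaps) rotates at the
#' configured speed; at each jump frame all gap orientations are reassigned
#' and the rotation direction is re-drawn uniformly. Isolated trials carry
#' the matched trend's distance trace and jump schedule but no flanker
#' channels.
#'
#' @param config A [paradigm_config()].
#' @param condition `"flanked"` or `"isolated"`.
#' @param trend `"increasing"` or `"decreasing"` distance trend (for isolated
#'   trials: the matched "invisible flanker" trend).
#' @param seed Integer seed for this trial's randomness.
#' @return A tibble with one row per frame: `frame`, `time_s`, `condition`,
#'   `trend`, `target_ori_deg`, `flank1_ori_deg`..`flank4_ori_deg` (NA when
#'   isolated), `distance_deg`, `direction`, `is_jump`.
#' @export
generate_continuous_trial <- function(config, condition = c("flanked", "isolated"),
                                      trend = c("increasing", "decreasing"),
                                      seed = config$seed) {
  condition <- match.arg(condition)
  trend <- match.arg(trend)
  n <- round(config$sample_rate_hz * config$trial_duration_s)
  step <- config$rotation_speed_deg_s / config$sample_rate_hz
  dist <- distance_trajectory(config, trend)
  jumps <- jump_frames_for_trend(config, trend)
  jumps <- jumps[jumps > 1L & jumps <= n]

  with_seed(seed, {
    seg_starts <- c(1L, jumps)
    seg_ends <- c(jumps - 1L, n)
    target <- numeric(n)
    gap_off <- numeric(n)
    direction <- integer(n)
    for (k in seq_along(seg_starts)) {
      i0 <- seg_starts[k]; i1 <- seg_ends[k]
      ori0 <- draw_target_orientation(1)
      dir0 <- sample(c(-1L, 1L), 1)
      gaps <- assign_flanker_gaps(ori0, config$flanker_gap_sd_deg)
      idx <- i0:i1
      target[idx] <- wrap_360(ori0 + dir0 * step * (idx - i0))
      gap_off[idx] <- wrap_360(gaps[1] - ori0)
      direction[idx] <- dir0
    }
  })

  flank1 <- wrap_360(target + gap_off)
  is_jump <- rep(FALSE, n)
  is_jump[jumps] <- TRUE
  out <- tibble::tibble(
    frame = seq_len(n),
    time_s = (seq_len(n) - 1) / config$sample_rate_hz,
    condition = condition,
    trend = trend,
    target_ori_deg = target,
    flank1_ori_deg = flank1,
    flank2_ori_deg = wrap_360(flank1 + 90),
    flank3_ori_deg = wrap_360(flank1 + 180),
    flank4_ori_deg = wrap_360(flank1 + 270),
    distance_deg = dist,
    direction = direction,
    is_jump = is_jump
  )
  if (condition == "isolated") {
    out$flank1_ori_deg <- out$flank2_ori_deg <- out$flank3_ori_deg <- out$flank4_ori_deg <- NA_real_
  }
  out
}

#' Build one continuous-paradigm block schedule
#'
#' Eight flanked trials (half increasing, half decreasing distance) plus four
#' isolated trials (half matched to each trend's jump schedule), in random
#' order.
#'
#' @param config A [paradigm_config()].
#' @param seed Integer seed for the ordering and per-trial sub-seeds.
#' @return A tibble of trial specs: `trial`, `paradigm`, `condition`,
#'   `trend`, `seed`.
#' @export
build_block_schedule <- function(config, seed = config$seed) {
  nf <- config$n_flanked_per_block
  ni <- config$n_isolated_per_block
  specs <- tibble::tibble(
    paradigm = "continuous",
    condition = c(rep("flanked", nf), rep("isolated", ni)),
    trend = c(rep(c("increasing", "decreasing"), each = nf / 2),
              rep(c("increasing", "decreasing"), each = ni / 2))
  )
  with_seed(derive_seed(seed, 101L), {
    specs <- specs[sample.int(nrow(specs)), ]
  })
  specs$trial <- seq_len(nrow(specs))
  specs$seed <- vapply(specs$trial, function(i) derive_seed(seed, 7L, i), integer(1))
  specs[, c("trial", "paradigm", "condition", "trend", "seed")]
}

#' Build the trial-based schedule
#'
#' Seven flanked distances plus the isolated condition, each repeated
#' `trial_based_reps` times, in random order.
#'
#' @inheritParams build_block_schedule
#' @return A tibble of trial specs: `trial`, `paradigm`, `condition`,
#'   `distance_deg` (NA for isolated), `seed`.
#' @export
build_trial_based_schedule <- function(config, seed = config$seed) {
  specs <- tibble::tibble(
    paradigm = "trial_based",
    condition = c(rep("flanked", length(config$trial_based_distances_deg)), "isolated"),
    distance_deg = c(config$trial_based_distances_deg, NA_real_)
  )
  specs <- specs[rep(seq_len(nrow(specs)), each = config$trial_based_reps), ]
  with_seed(derive_seed(seed, 202L), {
    specs <- specs[sample.int(nrow(specs)), ]
  })
  specs$trial <- seq_len(nrow(specs))
  specs$seed <- vapply(specs$trial, function(i) derive_seed(seed, 11L, i), integer(1))
  specs[, c("trial", "paradigm", "condition", "distance_deg", "seed")]
}
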