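# Synthetic tracking observer: motor latency + first-order pursuit lag +
# distance-dependent correlated report noise + condition-specific exponential
# reacquisition after orientation jumps. The model is the simplest one for
# which the analysis-side estimators (hinged noise profile, exponential decay,
# Von Mises perceptual error) are correctly specified.

#' Report-noise SD as a function of target-flanker distance
#'
#' Hinged profile: baseline noise plus a linear penalty for flanker intrusion
#' below the observer's true crowding extent.
#'
#' @param distance_deg Distance(s), deg. `Inf` (or any value at or beyond the
#'   hinge) gives the uncrowded baseline.
#' @param observer An [observer_config()].
#' @return Circular noise SD(s), deg.
#' @export
#' @examples
#' perceived_noise_sd(c(0, 2.5, 5, Inf), observer_config())
perceived_noise_sd <- function(distance_deg, observer) {
  observer$baseline_noise_sd_deg +
    observer$crowding_slope_deg_per_deg *
      pmax(0, observer$crowding_extent_deg - distance_deg)
}

recovery_rate_for <- function(observer, condition) {
  if (condition == "flanked") observer$recovery_rate_flanked_per_s
  else observer$recovery_rate_isolated_per_s
}

#' Simulate a tracking response to a continuous stimulus trial
#'
#' The observer follows the predictable smooth rotation with a predictive,
#' velocity-matched pursuit (the first-order lag is compensated on the ramp,
#' so it produces no steady-state error). Orientation jumps are
#' unpredictable: at each jump the response initially keeps the pre-jump
#' course; the observer re-identifies the target after the motor latency
#' plus an exponential waiting time with the condition's recovery rate, so
#' the expected absolute error decays as `exp(-b t)` toward the noise floor.
#' An Ornstein-Uhlenbeck orientation-noise channel whose stationary SD is
#' the hinged function of the current target-flanker distance is added at
#' the report stage. All arithmetic is circular.
#'
#' @param stimulus A stimulus trial from [generate_continuous_trial()].
#' @param observer An [observer_config()].
#' @param seed Integer seed for the response noise.
#' @return A tibble (tracking trace): `frame`, `time_s`, `condition`,
#'   `trend`, `target_ori_deg`, `response_ori_deg`, `distance_deg`,
#'   `direction`, `is_jump`, `gap_mask`.
#' @export
simulate_tracking_response <- function(stimulus, observer, seed = observer$seed) {
  n <- nrow(stimulus)
  if (n < 1L) stop("simulate_tracking_response(): empty stimulus", call. = FALSE)
  dt <- if (n > 1L) stimulus$time_s[2] - stimulus$time_s[1] else 1
  condition <- stimulus$condition[1]
  target <- stimulus$target_ori_deg
  jumps <- which(stimulus$is_jump)
  b <- recovery_rate_for(observer, condition)
  step_dir <- c(0, wrap_180(diff(target)))  # advance from frame i-1 to i

  # Tracking-error residual. The smooth rotation is predictable and is
  # followed by a lag-compensating pursuit with matched velocity, so the
  # first-order pursuit lag produces no steady-state error on the ramp;
  # jumps are not predictable. At a jump the error instantly becomes the
  # wrapped offset between the projected old course and the new orientation
  # (the error is imposed by the stimulus, not by the motor system). The
  # observer re-identifies the target after the motor latency plus an
  # exponential waiting time with the condition's recovery rate, so the
  # expected absolute error after a jump decays toward the noise floor
  # exactly as exp(-b t) (a per-jump gradual decay would make the mean
  # absolute error non-exponential near the floor and bias the decay fit).
  L <- round(observer$motor_latency_ms / 1000 / dt)
  is_j <- stimulus$is_jump
  jumps_idx <- which(is_j)
  waits <- with_seed(derive_seed(seed, 29L), {
    if (b > 0) stats::rexp(max(length(jumps_idx), 1L), rate = b) else rep(Inf, max(length(jumps_idx), 1L))
  })
  r <- numeric(n)
  reacq <- Inf
  jk <- 0L
  for (i in seq_len(n)[-1]) {
    if (is_j[i]) {
      jk <- jk + 1L
      step_prev <- if (i >= 3L && !is_j[i - 1]) step_dir[i - 1] else 0
      r[i] <- wrap_180(target[i - 1] + r[i - 1] + step_prev - target[i])
      reacq <- i + L + max(1, round(waits[jk] / dt))
    } else {
      r[i] <- if (i >= reacq) 0 else r[i - 1]
    }
  }
  pursuit_resid <- r

  # Report-noise channel: OU process, stationary SD sigma(d(t)).
  sigma <- if (condition == "flanked") {
    perceived_noise_sd(stimulus$distance_deg, observer)
  } else {
    rep(perceived_noise_sd(Inf, observer), n)
  }
  tau_n <- observer$noise_time_constant_ms / 1000
  phi <- if (tau_n <= 0) 0 else exp(-dt / tau_n)
  noise <- with_seed(seed, {
    z <- stats::rnorm(n)
    nn <- numeric(n)
    nn[1] <- sigma[1] * z[1]
    w <- sqrt(1 - phi^2)
    for (i in seq_len(n)[-1]) nn[i] <- phi * nn[i - 1] + w * sigma[i] * z[i]
    nn
  })

  tibble::tibble(
    frame = stimulus$frame,
    time_s = stimulus$time_s,
    condition = condition,
    trend = stimulus$trend,
    target_ori_deg = target,
    response_ori_deg = wrap_360(target + pursuit_resid + noise),
    distance_deg = stimulus$distance_deg,
    direction = stimulus$direction,
    is_jump = stimulus$is_jump,
    gap_mask = FALSE
  )
}

#' Simulate one trial-based report
#'
#' Reports are Von Mises around the true target orientation with a
#' concentration set by the distance-dependent noise hinge (isolated trials
#' use the uncrowded baseline).
#'
#' @param target_ori_deg True target gap orientation, deg.
#' @param distance_deg Target-flanker distance, deg; `NA` or `Inf` for
#'   isolated.
#' @param observer An [observer_config()].
#' @param seed Integer seed.
#' @return Reported orientation in `[0, 360)`.
#' @export
simulate_trial_based_response <- function(target_ori_deg, distance_deg, observer,
                                          seed = observer$seed) {
  d <- if (is.na(distance_deg)) Inf else distance_deg
  kappa <- if (is.function(observer$trial_based_kappa_fn)) {
    observer$trial_based_kappa_fn(d)
  } else {
    sigma_rad <- deg2rad(perceived_noise_sd(d, observer))
    if (sigma_rad <= 0) Inf else 1 / sigma_rad^2
  }
  with_seed(seed, rvonmises(1, target_ori_deg, kappa))
}

#' Generate a full synthetic dataset
#'
#' Per synthetic observer: `n_runs` continuous blocks (each 8 flanked + 4
#' isolated trials by default) and one trial-based session (200 trials by
#' default). Fully reproducible from `seed`.
#'
#' @param config A [paradigm_config()].
#' @param observers List of [observer_config()] objects (one per synthetic
#'   participant).
#' @param n_runs Continuous-paradigm runs per observer.
#' @param seed Root integer seed.
#' @return A list with class `"crowding_dataset"`: `continuous` (tracking
#'   traces, long tibble with `observer`, `run`, `trial` keys) and
#'   `trial_based` (one row per report).
#' @export
generate_dataset <- function(config, observers, n_runs = 2, seed = 1L) {
  stopifnot(n_runs >= 1, length(observers) >= 1)
  cont <- vector("list", 0)
  tb <- vector("list", 0)
  for (oi in seq_along(observers)) {
    obs <- observers[[oi]]
    for (run in seq_len(n_runs)) {
      sched <- build_block_schedule(config, seed = derive_seed(seed, oi, run))
      traces <- purrr::pmap(sched, function(trial, paradigm, condition, trend, seed) {
        stim <- generate_continuous_trial(config, condition, trend, seed = seed)
        resp <- simulate_tracking_response(stim, obs, seed = derive_seed(seed, 13L))
        resp$trial <- trial
        resp
      })
      block <- dplyr::bind_rows(traces)
      block$observer <- oi
      block$run <- run
      cont[[length(cont) + 1L]] <- block
    }
    sched_tb <- build_trial_based_schedule(config, seed = derive_seed(seed, oi, 0L))
    reports <- purrr::pmap_dfr(sched_tb, function(trial, paradigm, condition, distance_deg, seed) {
      target <- with_seed(derive_seed(seed, 17L), draw_target_orientation(1))
      rep_ori <- simulate_trial_based_response(target, distance_deg, obs,
                                               seed = derive_seed(seed, 19L))
      tibble::tibble(trial = trial, condition = condition,
                     distance_deg = distance_deg,
                     target_ori_deg = target, report_ori_deg = rep_ori)
    })
    reports$observer <- oi
    tb[[length(tb) + 1L]] <- reports
  }
  continuous <- dplyr::bind_rows(cont)
  trial_based <- dplyr::bind_rows(tb)
  cols <- c("observer", "run", "trial", "frame", "time_s", "condition", "trend",
            "target_ori_deg", "response_ori_deg", "distance_deg", "direction",
            "is_jump", "gap_mask")
  structure(
    list(continuous = continuous[, cols],
         trial_based = trial_based[, c("observer", "trial", "condition",
                                       "distance_deg", "target_ori_deg",
                                       "report_ori_deg")],
         config = config, observers = observers, n_runs = n_runs, seed = seed),
    class = "crowding_dataset"
  )
}

#' @export
print.crowding_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic crowding dataset: %d observer(s), %d continuous run(s), %d tracking frames, %d trial-based reports\n",
    length(x$observers), x$n_runs, nrow(x$continuous), nrow(x$trial_based)))
  invisible(x)
}
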