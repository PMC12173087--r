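#' Paradigm configuration
#'
#' Parameters of the continuous and trial-based crowding paradigms. Defaults
#' reproduce the study conditions: a Landolt-C target at 10 deg eccentricity
#' rotating at 72 deg/s on a 144 Hz display, 40-s trials, a target-flanker
#' distance sweep at 0.13 deg/s between 0 and 5 deg with orientation
#' reassignments ("jumps") at five preselected distances, blocks of
#' 8 flanked + 4 isolated continuous trials, and a trial-based session of
#' 8 conditions x 25 repetitions = 200 trials.
#'
#' @param sample_rate_hz Display/response sampling rate, Hz.
#' @param trial_duration_s Continuous trial duration, seconds.
#' @param rotation_speed_deg_s Target (and flanker) rotation speed, deg/s.
#' @param distance_speed_deg_s Target-flanker distance sweep speed, deg/s.
#' @param distance_min_deg,distance_max_deg Edge-to-edge distance range, deg.
#' @param jump_distances_deg Distances at which gap orientations are
#'   reassigned, deg; strictly inside the distance range, sorted ascending.
#' @param flanker_gap_sd_deg SD of the normal draw centring the first flanker
#'   gap on the target gap orientation, deg.
#' @param eccentricity_deg Target eccentricity, deg (metadata only).
#' @param n_flanked_per_block,n_isolated_per_block Continuous trials per
#'   block; flanked count must be even (half increasing, half decreasing).
#' @param trial_based_distances_deg Flanked distances of the trial-based
#'   paradigm, deg.
#' @param trial_based_reps Repetitions per trial-based condition.
#' @param seed Integer seed for schedule-level randomness.
#' @return An object of class `"paradigm_config"` (a named list).
#' @export
#' @examples
#' cfg <- paradigm_config()
#' cfg$rotation_speed_deg_s
paradigm_config <- function(sample_rate_hz = 144,
                            trial_duration_s = 40,
                            rotation_speed_deg_s = 72,
                            distance_speed_deg_s = 0.13,
                            distance_min_deg = 0,
                            distance_max_deg = 5,
                            jump_distances_deg = c(0.31, 0.35, 1.35, 2.20, 3.37),
                            flanker_gap_sd_deg = 45,
                            eccentricity_deg = 10,
                            n_flanked_per_block = 8,
                            n_isolated_per_block = 4,
                            trial_based_distances_deg = c(0, 0.31, 0.35, 1.35, 2.20, 3.37, 5),
                            trial_based_reps = 25,
                            seed = 1L) {
  cfg <- structure(
    list(
      sample_rate_hz = sample_rate_hz,
      trial_duration_s = trial_duration_s,
      rotation_speed_deg_s = rotation_speed_deg_s,
      distance_speed_deg_s = distance_speed_deg_s,
      distance_min_deg = distance_min_deg,
      distance_max_deg = distance_max_deg,
      jump_distances_deg = jump_distances_deg,
      flanker_gap_sd_deg = flanker_gap_sd_deg,
      eccentricity_deg = eccentricity_deg,
      n_flanked_per_block = n_flanked_per_block,
      n_isolated_per_block = n_isolated_per_block,
      trial_based_distances_deg = trial_based_distances_deg,
      trial_based_reps = trial_based_reps,
      seed = as.integer(seed)
    ),
    class = "paradigm_config"
  )
  validate_paradigm_config(cfg)
}

validate_paradigm_config <- function(cfg) {
  fail <- function(...) stop("paradigm_config: ", sprintf(...), call. = FALSE)
  if (!is.numeric(cfg$sample_rate_hz) || cfg$sample_rate_hz <= 0) {
    fail("sample_rate_hz must be > 0 (got %s)", cfg$sample_rate_hz)
  }
  if (cfg$trial_duration_s <= 0) fail("trial_duration_s must be > 0")
  if (cfg$rotation_speed_deg_s < 0) fail("rotation_speed_deg_s must be >= 0")
  if (cfg$distance_speed_deg_s < 0) fail("distance_speed_deg_s must be >= 0")
  if (cfg$distance_min_deg >= cfg$distance_max_deg) {
    fail("distance_min_deg must be < distance_max_deg")
  }
  jd <- cfg$jump_distances_deg
  if (length(jd)) {
    if (is.unsorted(jd, strictly = TRUE)) fail("jump_distances_deg must be sorted strictly ascending")
    if (any(jd <= cfg$distance_min_deg | jd >= cfg$distance_max_deg)) {
      fail("jump_distances_deg must lie strictly inside (%g, %g)",
           cfg$distance_min_deg, cfg$distance_max_deg)
    }
  }
  if (cfg$flanker_gap_sd_deg < 0) fail("flanker_gap_sd_deg must be >= 0")
  if (cfg$n_flanked_per_block %% 2 != 0) {
    fail("n_flanked_per_block must be even (half increasing, half decreasing)")
  }
  if (cfg$n_isolated_per_block %% 2 != 0) {
    fail("n_isolated_per_block must be even (half matched to each trend)")
  }
  if (cfg$trial_based_reps < 0) fail("trial_based_reps must be >= 0")
  cfg
}

#' Synthetic observer configuration
#'
#' Generative parameters of the simulated tracking observer: a motor latency,
#' a first-order pursuit lag, distance-dependent circular report noise with a
#' hinge at the true crowding extent, and condition-specific exponential
#' recovery from orientation jumps.
#'
#' @param motor_latency_ms Delay between a stimulus change and the response
#'   reacting to it, ms.
#' @param tracking_time_constant_ms Time constant of the first-order pursuit
#'   lag, ms.
#' @param baseline_noise_sd_deg Circular SD of report noise when the target
#'   is effectively uncrowded (distance >= `crowding_extent_deg`), deg.
#' @param crowding_extent_deg True crowding extent (noise hinge location), deg.
#' @param crowding_slope_deg_per_deg Added noise SD per degree of flanker
#'   intrusion below the hinge, deg/deg.
#' @param recovery_rate_flanked_per_s,recovery_rate_isolated_per_s Exponential
#'   decay rates of the post-jump tracking error, 1/s.
#' @param noise_time_constant_ms Correlation time of the report-noise process
#'   (Ornstein-Uhlenbeck), ms; gives tracking errors the smooth
#'   autocorrelation seen in real mouse traces.
#' @param trial_based_kappa_fn Mapping from distance (deg) to the Von Mises
#'   concentration of trial-based reports. Default ties kappa to the same
#'   noise hinge: `kappa = 1 / sigma(d)^2` with sigma in radians.
#' @param seed Integer seed.
#' @return An object of class `"observer_config"`.
#' @export
observer_config <- function(motor_latency_ms = 280,
                            tracking_time_constant_ms = 150,
                            baseline_noise_sd_deg = 10,
                            crowding_extent_deg = 5,
                            crowding_slope_deg_per_deg = 8,
                            recovery_rate_flanked_per_s = 2.0,
                            recovery_rate_isolated_per_s = 3.5,
                            noise_time_constant_ms = 300,
                            trial_based_kappa_fn = NULL,
                            seed = 1L) {
  obs <- structure(
    list(
      motor_latency_ms = motor_latency_ms,
      tracking_time_constant_ms = tracking_time_constant_ms,
      baseline_noise_sd_deg = baseline_noise_sd_deg,
      crowding_extent_deg = crowding_extent_deg,
      crowding_slope_deg_per_deg = crowding_slope_deg_per_deg,
      recovery_rate_flanked_per_s = recovery_rate_flanked_per_s,
      recovery_rate_isolated_per_s = recovery_rate_isolated_per_s,
      noise_time_constant_ms = noise_time_constant_ms,
      trial_based_kappa_fn = trial_based_kappa_fn,
      seed = as.integer(seed)
    ),
    class = "observer_config"
  )
  validate_observer_config(obs)
}

validate_observer_config <- function(obs) {
  fail <- function(...) stop("observer_config: ", sprintf(...), call. = FALSE)
  nonneg <- c("motor_latency_ms", "tracking_time_constant_ms",
              "baseline_noise_sd_deg", "crowding_slope_deg_per_deg",
              "recovery_rate_flanked_per_s", "recovery_rate_isolated_per_s",
              "noise_time_constant_ms")
  for (f in nonneg) {
    if (!is.numeric(obs[[f]]) || obs[[f]] < 0) fail("%s must be >= 0", f)
  }
  if (obs$crowding_extent_deg < 0) fail("crowding_extent_deg must be >= 0")
  if (!is.null(obs$trial_based_kappa_fn) && !is.function(obs$trial_based_kappa_fn)) {
    fail("trial_based_kappa_fn must be NULL or a function")
  }
  obs
}

#' Log-spaced jump distances
#'
#' Builds jump distances equally spaced on a log scale between an inner
#' touching separation and an outer separation, then re-expressed relative to
#' touching (the construction described for the preselected distances; note
#' it does not reproduce the listed defaults, which are kept verbatim).
#'
#' @param n Number of distances (endpoints included before shifting).
#' @param inner_deg,outer_deg Log-scale endpoints, deg.
#' @return Numeric vector of length `n`, starting at 0.
#' @export
#' @examples
#' log_spaced_jump_distances()
log_spaced_jump_distances <- function(n = 5, inner_deg = 0.8, outer_deg = 5.8) {
  exp(seq(log(inner_deg), log(outer_deg), length.out = n)) - inner_deg
}

config_fields <- function(class) {
  switch(class,
    paradigm = setdiff(names(formals(paradigm_config)), "..."),
    observer = setdiff(names(formals(observer_config)), "...")
  )
}

#' Read paradigm and observer configuration from YAML or JSON
#'
#' The file may contain top-level keys `paradigm` and/or `observers` (a list
#' of observer entries). Missing fields take their defaults; unknown keys are
#' an error, reported by name.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. An empty file yields
#'   all defaults.
#' @return List with `paradigm` (a [paradigm_config()]) and `observers`
#'   (list of [observer_config()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  allowed_top <- c("paradigm", "observers")
  bad <- setdiff(names(raw), allowed_top)
  if (length(bad)) {
    stop("config: unknown top-level keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  par_raw <- raw$paradigm %||% list()
  bad <- setdiff(names(par_raw), config_fields("paradigm"))
  if (length(bad)) {
    stop("config: unknown paradigm keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  paradigm <- do.call(paradigm_config, par_raw)
  obs_raw <- raw$observers %||% list(list())
  if (!is.null(names(obs_raw))) obs_raw <- list(obs_raw)  # single unwrapped entry
  observers <- lapply(obs_raw, function(o) {
    o <- as.list(o)
    bad <- setdiff(names(o), config_fields("observer"))
    if (length(bad)) {
      stop("config: unknown observer keys: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    do.call(observer_config, o)
  })
  list(paradigm = paradigm, observers = observers)
}

#' Write configuration to YAML
#'
#' Round-trips through [read_config()].
#'
#' @param paradigm A [paradigm_config()].
#' @param observers List of [observer_config()] objects (optional).
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(paradigm, observers = list(), path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.function, logical(1))]  # kappa_fn is not serialisable
  }
  out <- list(paradigm = strip(paradigm))
  if (length(observers)) out$observers <- lapply(observers, strip)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
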