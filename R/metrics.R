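# Headline quantities: cosine-similarity tracking performance, crowding
# extents (regression-intersection and hinged-line), Von Mises perceptual
# error, exponential-decay recovery rates, sequential-t-test recovery times.

#' Cosine similarity between stimulus and response orientation series
#'
#' Normalised inner product of the orientation unit vectors; because every
#' term has unit magnitude this reduces exactly to the mean cosine of the
#' report error. 1 means perfect tracking, -1 antipodal responses.
#'
#' @param theta_stimulus_deg,theta_response_deg Equal-length orientation
#'   series, degrees. Pairs with a missing value are dropped.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' th <- runif(100, 0, 360)
#' cosine_similarity(th, th)  # 1
cosine_similarity <- function(theta_stimulus_deg, theta_response_deg) {
  if (length(theta_stimulus_deg) != length(theta_response_deg)) {
    stop("cosine_similarity(): series lengths differ", call. = FALSE)
  }
  ok <- !is.na(theta_stimulus_deg) & !is.na(theta_response_deg)
  s <- deg2rad(theta_stimulus_deg[ok])
  r <- deg2rad(theta_response_deg[ok])
  if (!length(s)) stop("cosine_similarity(): empty series", call. = FALSE)
  num <- sum(cos(s) * cos(r) + sin(s) * sin(r))
  den <- sqrt(sum(cos(s)^2 + sin(s)^2)) * sqrt(sum(cos(r)^2 + sin(r)^2))
  num / den
}

#' Linear regression of report error on target-flanker distance
#'
#' Ordinary least squares of per-frame absolute report error on distance.
#'
#' @param abs_error_deg Absolute errors, deg.
#' @param distance_deg Matching distances, deg.
#' @param condition Optional condition label stored with the fit.
#' @return An object of class `"line_fit"`: `slope`, `intercept`,
#'   `condition`, `n`.
#' @export
fit_error_vs_distance <- function(abs_error_deg, distance_deg, condition = NA_character_) {
  ok <- !is.na(abs_error_deg) & !is.na(distance_deg)
  y <- abs_error_deg[ok]; x <- distance_deg[ok]
  if (length(unique(x)) < 2L) {
    stop("fit_error_vs_distance(): need >= 2 distinct distances", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         condition = condition, n = length(y)),
    class = "line_fit"
  )
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("Line fit (%s): error = %.3f + %.3f * distance (n = %d)\n",
              x$condition, x$intercept, x$slope, x$n))
  invisible(x)
}

#' @method tidy line_fit
#' @export
tidy.line_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 condition = x$condition)
}

new_crowding_extent <- function(extent, raw, method, flanked_fit, baseline, status = "ok") {
  structure(
    list(extent_deg = extent, raw_extent_deg = raw, method = method,
         flanked_fit = flanked_fit, baseline = baseline, status = status),
    class = "crowding_extent"
  )
}

#' @export
print.crowding_extent <- function(x, ...) {
  cat(sprintf("Crowding extent: %.3f deg (%s%s)\n", x$extent_deg, x$method,
              if (x$status != "ok") paste0("; ", x$status) else ""))
  invisible(x)
}

#' @method tidy crowding_extent
#' @export
tidy.crowding_extent <- function(x, ...) {
  tibble::tibble(extent_deg = x$extent_deg, raw_extent_deg = x$raw_extent_deg,
                 method = x$method, status = x$status)
}

#' Crowding extent from two regression lines (continuous paradigm)
#'
#' Intersects the flanked and isolated error-versus-distance regression
#' lines; the crossing distance is the critical spacing at which flankers
#' begin to impair target perception. The raw intersection is retained; the
#' reported extent is clipped to `[0, max_distance]`.
#'
#' @param flanked_fit,isolated_fit [fit_error_vs_distance()] results.
#' @param max_distance_deg Largest tested distance, deg.
#' @return A `"crowding_extent"` object.
#' @export
#' @examples
#' fl <- structure(list(slope = -2, intercept = 12, condition = "flanked", n = 2),
#'                 class = "line_fit")
#' iso <- structure(list(slope = 0, intercept = 2, condition = "isolated", n = 2),
#'                  class = "line_fit")
#' crowding_extent_continuous(fl, iso, 5)$extent_deg  # 5
crowding_extent_continuous <- function(flanked_fit, isolated_fit, max_distance_deg) {
  ds <- flanked_fit$slope - isolated_fit$slope
  if (abs(ds) <= 1e-9) {
    stop(sprintf(
      "crowding_extent_continuous(): regression lines are parallel (flanked slope %.6g, isolated slope %.6g)",
      flanked_fit$slope, isolated_fit$slope), call. = FALSE)
  }
  raw <- (isolated_fit$intercept - flanked_fit$intercept) / ds
  new_crowding_extent(
    extent = min(max(raw, 0), max_distance_deg), raw = raw,
    method = "continuous_intersection",
    flanked_fit = flanked_fit, baseline = isolated_fit
  )
}

#' Von Mises perceptual error
#'
#' Maximum-likelihood Von Mises fit to signed report errors; the perceptual
#' error is the circular SD implied by the fitted concentration,
#' `sqrt(-2 log(Rbar))` in degrees.
#'
#' @param signed_errors_deg Signed report errors, deg.
#' @param distance_deg Optional distance label, deg.
#' @return An object of class `"perceptual_error"`: `distance_deg`,
#'   `circular_sd_deg`, `kappa`, `n`.
#' @export
perceptual_error_vonmises <- function(signed_errors_deg, distance_deg = NA_real_) {
  x <- signed_errors_deg[!is.na(signed_errors_deg)]
  if (length(x) < 5L) {
    stop("perceptual_error_vonmises(): need at least 5 errors", call. = FALSE)
  }
  vm <- fit_vonmises(x)
  structure(
    list(distance_deg = distance_deg, circular_sd_deg = vm$circular_sd_deg,
         kappa = vm$kappa, mu_deg = vm$mu_deg, n = vm$n),
    class = "perceptual_error"
  )
}

#' @export
print.perceptual_error <- function(x, ...) {
  cat(sprintf("Perceptual error: sigma = %.2f deg (kappa = %.3f, n = %d)\n",
              x$circular_sd_deg, x$kappa, x$n))
  invisible(x)
}

#' Crowding extent from trial-based perceptual errors
#'
#' `method = "intersection"` (the conventional analysis) fits an OLS line
#' through the flanked (distance, perceptual error) points and intersects it
#' with the flat isolated baseline. `method = "hinged"` fits a broken-stick
#' model `sigma(d) = baseline + s * max(0, h - d)` by least squares and
#' reports the hinge `h`; this remains consistent when the true extent lies
#' inside the tested range (where a single line through sloped-plus-flat
#' points is biased).
#'
#' @param perceptual A data frame with columns `distance_deg` and
#'   `circular_sd_deg` for the flanked conditions (>= 3 distances), e.g.
#'   built from [perceptual_error_vonmises()] fits.
#' @param baseline_sd_deg Isolated-condition perceptual error, deg.
#' @param max_distance_deg Largest tested distance, deg.
#' @param method `"intersection"` or `"hinged"`.
#' @return A `"crowding_extent"` object.
#' @export
crowding_extent_trial_based <- function(perceptual, baseline_sd_deg,
                                        max_distance_deg,
                                        method = c("intersection", "hinged")) {
  method <- match.arg(method)
  d <- perceptual$distance_deg
  s <- perceptual$circular_sd_deg
  if (length(unique(d)) < 3L) {
    stop("crowding_extent_trial_based(): need >= 3 flanked distances", call. = FALSE)
  }
  if (method == "hinged") {
    h <- fit_hinge(d, s, baseline_sd_deg, max_h = max_distance_deg)
    return(new_crowding_extent(
      extent = min(max(h$hinge, 0), max_distance_deg), raw = h$hinge,
      method = "trial_based_hinged",
      flanked_fit = h, baseline = baseline_sd_deg, status = h$status
    ))
  }
  fit <- fit_error_vs_distance(s, d, condition = "flanked")
  if (abs(fit$slope) <= 1e-9 && abs(fit$intercept - baseline_sd_deg) <= 1e-9) {
    return(new_crowding_extent(0, 0, "trial_based_intersection", fit,
                               baseline_sd_deg, status = "degenerate: line equals baseline"))
  }
  if (fit$slope >= 0) {
    return(new_crowding_extent(max_distance_deg, NA_real_,
                               "trial_based_intersection", fit, baseline_sd_deg,
                               status = "non-negative slope: no crossing below baseline"))
  }
  raw <- (baseline_sd_deg - fit$intercept) / fit$slope
  new_crowding_extent(min(max(raw, 0), max_distance_deg), raw,
                      "trial_based_intersection", fit, baseline_sd_deg)
}

# Least-squares broken stick with the flat arm fixed at `baseline`:
# y(d) = baseline + s * max(0, h - d), s >= 0. The hinge is profiled on a
# grid (slope has a closed form given h).
fit_hinge <- function(d, y, baseline, max_h, weights = NULL, grid_step = 0.01) {
  if (is.null(weights)) weights <- rep(1, length(d))
  ok <- !is.na(d) & !is.na(y) & weights > 0
  d <- d[ok]; y <- y[ok]; w <- weights[ok]
  yc <- y - baseline
  hs <- seq(grid_step, max_h, by = grid_step)
  best <- list(hinge = 0, slope = 0, sse = sum(w * yc^2), status = "degenerate: no excess over baseline")
  for (h in hs) {
    x <- pmax(0, h - d)
    sxx <- sum(w * x^2)
    if (sxx <= 0) next
    s <- max(0, sum(w * x * yc) / sxx)
    sse <- sum(w * (yc - s * x)^2)
    if (sse < best$sse - 1e-12) best <- list(hinge = h, slope = s, sse = sse, status = "ok")
  }
  best
}

#' Binned noise profile from continuous tracking errors
#'
#' Circular SD of signed report errors within distance bins, computed
#' separately per rotation direction (removing the direction-signed pursuit
#' lag offset) and pooled. This is the continuous-paradigm analogue of the
#' trial-based perceptual error.
#'
#' @param errors Error-series tibble with `signed_error_deg`,
#'   `distance_deg`, `direction`, and optionally `deleted`.
#' @param bin_width_deg Distance bin width, deg.
#' @param min_n Minimum frames per bin-direction cell.
#' @return A tibble: `distance_deg` (bin centre), `circular_sd_deg`, `n`.
#' @export
noise_profile <- function(errors, bin_width_deg = 0.25, min_n = 30) {
  if ("deleted" %in% names(errors)) errors <- errors[!errors$deleted, ]
  errors <- errors[!is.na(errors$signed_error_deg), ]
  bin <- floor(errors$distance_deg / bin_width_deg)
  key <- interaction(bin, errors$direction, drop = TRUE)
  cells <- split(errors$signed_error_deg, key)
  bins <- split(bin, key)
  rows <- purrr::map(seq_along(cells), function(i) {
    v <- cells[[i]]
    if (length(v) < min_n) return(NULL)
    tibble::tibble(bin = bins[[i]][1], sd2 = circ_sd(v)^2, n = length(v))
  })
  prof <- dplyr::bind_rows(rows)
  if (!nrow(prof)) stop("noise_profile(): no bin has enough data", call. = FALSE)
  prof |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      circular_sd_deg = sqrt(stats::weighted.mean(.data$sd2, .data$n)),
      n = sum(.data$n), .groups = "drop"
    ) |>
    dplyr::transmute(
      distance_deg = (.data$bin + 0.5) * bin_width_deg,
      circular_sd_deg = .data$circular_sd_deg, n = .data$n
    ) |>
    dplyr::arrange(.data$distance_deg)
}

#' Exponential decay fit to post-jump errors
#'
#' Fits `E(t) = a * exp(-b t) + c` by bounded nonlinear least squares
#' (Levenberg-Marquardt, all parameters >= 0). `a` is the typical initial
#' error magnitude, `b` the recovery rate (1/s), `c` the stable baseline.
#'
#' @param mean_error_deg Mean absolute error per post-jump sample, deg.
#' @param dt_s Sample interval, s.
#' @param motor_corrected Logical flag stored with the fit (the corrected
#'   variant fits samples 41..300, i.e. from ~280 ms after the jump).
#' @param start_time_s Time of the first sample relative to jump onset, s.
#' @return An object of class `"decay_fit"`: `a_deg`, `b_per_s`, `c_deg`,
#'   `rmse_deg`, `motor_corrected`, plus `fitted` values.
#' @export
fit_exponential_decay <- function(mean_error_deg, dt_s, motor_corrected = FALSE,
                                  start_time_s = 0) {
  y <- mean_error_deg
  ok <- !is.na(y)
  t <- start_time_s + (seq_along(y) - 1) * dt_s
  y <- y[ok]; t <- t[ok]
  if (length(y) < 10L) {
    stop("fit_exponential_decay(): need >= 10 samples", call. = FALSE)
  }
  if (stats::sd(y) < 1e-12) {
    return(new_decay_fit(0, 0, mean(y), 0, motor_corrected, rep(mean(y), length(y)), t))
  }
  tail_mean <- mean(utils::tail(y, max(5L, length(y) %/% 5L)))
  a0 <- max(y[1] - tail_mean, 1e-3)
  starts <- list(list(a = a0, b = 1, c = max(tail_mean, 1e-3)))
  set_jitter <- function(f) list(a = a0 * f, b = f, c = max(tail_mean, 1e-3) / f)
  starts <- c(starts, lapply(c(0.3, 0.7, 1.5, 3, 6), set_jitter))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(-b * t) + c,
        start = st, lower = c(a = 0, b = 0, c = 0),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop(sprintf(
      "fit_exponential_decay(): no convergence after %d starts (n = %d, range = [%.2f, %.2f])",
      length(starts), length(y), min(y), max(y)), call. = FALSE)
  }
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  new_decay_fit(unname(cf["a"]), unname(cf["b"]), unname(cf["c"]),
                sqrt(mean(res^2)), motor_corrected, stats::fitted(fit), t)
}

new_decay_fit <- function(a, b, c, rmse, motor_corrected, fitted, t) {
  structure(
    list(a_deg = a, b_per_s = b, c_deg = c, rmse_deg = rmse,
         motor_corrected = motor_corrected, fitted = fitted, time_s = t),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Decay fit%s: E(t) = %.2f * exp(-%.3f t) + %.2f  (RMSE %.3f deg)\n",
              if (x$motor_corrected) " (motor-corrected)" else "",
              x$a_deg, x$b_per_s, x$c_deg, x$rmse_deg))
  invisible(x)
}

#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("a_deg", "b_per_s", "c_deg"),
                 estimate = c(x$a_deg, x$b_per_s, x$c_deg))
}

#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(a_deg = x$a_deg, b_per_s = x$b_per_s, c_deg = x$c_deg,
                 rmse_deg = x$rmse_deg, motor_corrected = x$motor_corrected)
}

#' Recovery time by sequential t-tests
#'
#' The last `baseline_samples` columns of the post-jump window matrix define
#' the stable-performance pool. Scanning forward from the first column, each
#' column's values (across jumps) are compared with the pool by a Welch
#' t-test; the first non-significant column marks the recovery time.
#'
#' @param windows A [extract_post_jump_windows()] result (stack window
#'   matrices across trials/participants beforehand for a pooled analysis).
#' @param alpha Significance level of the per-column tests.
#' @param baseline_samples Columns from the window end forming the stable
#'   pool.
#' @return An object of class `"recovery_time"`: `recovery_ms`, `recovered`
#'   (FALSE when no column is non-significant; the window end is then
#'   reported), `per_sample_p`, `alpha`, `baseline_window_samples`.
#' @export
recovery_time <- function(windows, alpha = 0.05, baseline_samples = 50) {
  W <- windows$window_matrix
  if (ncol(W) < baseline_samples) {
    stop("recovery_time(): fewer columns than baseline_samples", call. = FALSE)
  }
  if (nrow(W) < 2L) stop("recovery_time(): need >= 2 jumps", call. = FALSE)
  pool <- as.vector(W[, (ncol(W) - baseline_samples + 1L):ncol(W)])
  pool <- pool[!is.na(pool)]
  p <- rep(NA_real_, ncol(W))
  for (j in seq_len(ncol(W))) {
    v <- W[, j]; v <- v[!is.na(v)]
    if (length(v) < 2L) next
    p[j] <- tryCatch(stats::t.test(v, pool)$p.value,
                     error = function(e) if (isTRUE(all.equal(mean(v), mean(pool)))) 1 else 0)
    if (is.na(p[j])) p[j] <- if (isTRUE(all.equal(mean(v), mean(pool)))) 1 else 0
  }
  hit <- which(p > alpha)[1]
  recovered <- !is.na(hit)
  idx <- if (recovered) hit else ncol(W)
  structure(
    list(recovery_ms = windows$time_s[idx] * 1000, recovered = recovered,
         per_sample_p = p, alpha = alpha,
         baseline_window_samples = baseline_samples),
    class = "recovery_time"
  )
}

#' @export
print.recovery_time <- function(x, ...) {
  cat(sprintf("Recovery time: %.0f ms%s\n", x$recovery_ms,
              if (!x$recovered) " (never non-significant; window end)" else ""))
  invisible(x)
}
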