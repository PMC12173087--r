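# Error definition, flip-and-average, artifact cleaning, and post-jump
# window extraction.

#' Signed report error
#'
#' Wrapped difference response - stimulus, in `[-180, 180)` (the tie at the
#' antipode resolves to -180).
#'
#' @param theta_stimulus_deg,theta_response_deg Orientations in degrees.
#' @return Signed error(s), deg.
#' @export
#' @examples
#' report_error(350, 10)   # +20
#' report_error(0, 180)    # -180
report_error <- function(theta_stimulus_deg, theta_response_deg) {
  wrap_180(theta_response_deg - theta_stimulus_deg)
}

#' Per-frame error series for tracking traces
#'
#' Adds signed and absolute report error columns to tracking traces.
#'
#' @param traces Tracking traces from [simulate_tracking_response()] /
#'   [generate_dataset()] (any grouping columns are carried through).
#' @return The input tibble plus `signed_error_deg` and `abs_error_deg`.
#' @export
error_series <- function(traces) {
  traces$signed_error_deg <- report_error(traces$target_ori_deg, traces$response_ori_deg)
  traces$abs_error_deg <- abs(traces$signed_error_deg)
  traces
}

#' Flip and average error series across trials
#'
#' Decreasing-trend trials are reversed in time so that every trial shares a
#' common increasing-distance axis, then the absolute errors are averaged
#' frame-wise across trials (missing/deleted frames are ignored).
#'
#' @param trials Error-series tibble for one condition (from
#'   [error_series()]), with `trial`, `frame`, `trend`, `abs_error_deg`, and
#'   optionally a logical `deleted` column.
#' @return A tibble with one row per frame: `frame`, `time_s`,
#'   `distance_deg` (the common increasing axis), `abs_error_deg` (mean),
#'   `n_trials`.
#' @export
flip_and_average <- function(trials) {
  lens <- tapply(trials$frame, trials$trial, length)
  if (length(unique(lens)) != 1L) {
    stop("flip_and_average(): trials have unequal lengths", call. = FALSE)
  }
  n <- unname(lens[1])
  if (!"deleted" %in% names(trials)) trials$deleted <- FALSE
  ids <- unique(trials$trial)
  acc <- matrix(NA_real_, nrow = length(ids), ncol = n)
  dist_axis <- NULL
  for (k in seq_along(ids)) {
    tr <- trials[trials$trial == ids[k], ]
    tr <- tr[order(tr$frame), ]
    v <- ifelse(tr$deleted, NA_real_, tr$abs_error_deg)
    if (tr$trend[1] == "decreasing") v <- rev(v)
    acc[k, ] <- v
    if (is.null(dist_axis)) {
      dist_axis <- if (tr$trend[1] == "decreasing") rev(tr$distance_deg) else tr$distance_deg
    }
  }
  tibble::tibble(
    frame = seq_len(n),
    time_s = sort(unique(trials$time_s))[seq_len(n)],
    distance_deg = dist_axis,
    abs_error_deg = colMeans(acc, na.rm = TRUE),
    n_trials = colSums(!is.na(acc))
  )
}

#' Artifact cleaning from the isolated condition
#'
#' Detects dominant error peaks in the isolated trial (absolute error above
#' twice the SD of the isolated report errors) and marks, around each peak,
#' the contiguous segment where the absolute error stays above the isolated
#' mean error + 1 SD. Marked frames are deleted from both conditions so data
#' availability stays matched.
#'
#' @param isolated,flanked Equal-length error-series tibbles for one matched
#'   trial pair (must contain `signed_error_deg` and `abs_error_deg`).
#' @return List with `isolated` and `flanked` (inputs plus a logical
#'   `deleted` column), `mask` (logical vector), and `thresholds`
#'   (`peak`, `extend`, `fraction_removed`).
#' @export
clean_artifacts <- function(isolated, flanked) {
  if (nrow(isolated) != nrow(flanked)) {
    stop("clean_artifacts(): series lengths differ", call. = FALSE)
  }
  e <- isolated$signed_error_deg
  a <- isolated$abs_error_deg
  sd_iso <- stats::sd(e)
  mean_iso <- mean(e)
  mask <- rep(FALSE, length(a))
  peak_thr <- 2 * sd_iso
  ext_thr <- mean_iso + sd_iso
  if (is.finite(sd_iso) && sd_iso > 0) {
    peaks <- a > peak_thr
    if (any(peaks)) {
      above <- a > ext_thr
      runs <- rle(above)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (k in which(runs$values)) {
        seg <- starts[k]:ends[k]
        if (any(peaks[seg])) mask[seg] <- TRUE
      }
    }
  }
  isolated$deleted <- mask
  flanked$deleted <- mask
  list(
    isolated = isolated, flanked = flanked, mask = mask,
    thresholds = list(peak = peak_thr, extend = ext_thr,
                      fraction_removed = mean(mask))
  )
}

#' Extract post-jump error windows
#'
#' Aligns absolute report errors to each jump onset. Windows never read
#' across a subsequent jump boundary or past the trial end; short windows are
#' padded with `NA`. Optionally the first `skip_samples` columns are dropped
#' (motor-latency correction).
#'
#' @param abs_error_deg Per-frame absolute error vector for one trial (use
#'   `NA` for deleted frames if cleaned data are wanted).
#' @param jump_indices Frame indices of the jumps (1-based).
#' @param window_samples Window length in samples after each jump.
#' @param skip_samples Samples dropped at the window start (0 or 40).
#' @param dt_s Sample interval, seconds.
#' @return An object of class `"post_jump_windows"`: list with
#'   `window_matrix` (jumps x retained samples), `mean_error` (column means),
#'   `time_s` (time from jump onset for each retained column), `dt_s`,
#'   `skip_samples`.
#' @export
extract_post_jump_windows <- function(abs_error_deg, jump_indices,
                                      window_samples = 300, skip_samples = 0,
                                      dt_s = 1 / 144) {
  jump_indices <- sort(unique(jump_indices))
  if (!length(jump_indices)) {
    stop("extract_post_jump_windows(): empty jump list", call. = FALSE)
  }
  stopifnot(skip_samples >= 0, skip_samples < window_samples)
  n <- length(abs_error_deg)
  bounds <- c(jump_indices[-1] - 1L, n)  # last usable frame per window
  W <- matrix(NA_real_, nrow = length(jump_indices), ncol = window_samples)
  for (k in seq_along(jump_indices)) {
    j <- jump_indices[k]
    last <- min(j + window_samples - 1L, bounds[k])
    if (last >= j) W[k, seq_len(last - j + 1L)] <- abs_error_deg[j:last]
  }
  keep <- (skip_samples + 1L):window_samples
  W <- W[, keep, drop = FALSE]
  structure(
    list(
      window_matrix = W,
      mean_error = colMeans(W, na.rm = TRUE),
      time_s = (keep - 1L) * dt_s,
      dt_s = dt_s,
      skip_samples = skip_samples
    ),
    class = "post_jump_windows"
  )
}

#' @export
print.post_jump_windows <- function(x, ...) {
  cat(sprintf("Post-jump windows: %d jumps x %d samples (dt = %.4f s, %d skipped)\n",
              nrow(x$window_matrix), ncol(x$window_matrix), x$dt_s, x$skip_samples))
  invisible(x)
}
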