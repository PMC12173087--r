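# End-to-end analysis: per-run continuous analysis, trial-based analysis,
# group-level statistics, and file-based simulate / analyze / recover runs.

match_isolated_trial <- function(flanked_trials, isolated_by_trend) {
  # cycle flanked trials of a trend through the isolated trials of that trend
  out <- integer(length(flanked_trials))
  counters <- list(increasing = 0L, decreasing = 0L)
  for (k in seq_along(flanked_trials)) {
    trend <- names(flanked_trials)[k]
    pool <- isolated_by_trend[[trend]]
    counters[[trend]] <- counters[[trend]] %% length(pool) + 1L
    out[k] <- pool[counters[[trend]]]
  }
  out
}

# TRUE for frames within `window` samples after any jump (jump frame included).
post_jump_frames <- function(is_jump, window) {
  idx <- which(is_jump)
  out <- rep(FALSE, length(is_jump))
  for (j in idx) out[j:min(j + window - 1L, length(out))] <- TRUE
  out
}

# Pooled circular SD of signed errors, computed within rotation-direction
# groups (removes the direction-signed pursuit offset) and variance-pooled.
pooled_noise_sd <- function(errors) {
  if ("deleted" %in% names(errors)) errors <- errors[!errors$deleted, ]
  groups <- split(errors$signed_error_deg, errors$direction)
  sd2 <- vapply(groups, function(v) circ_sd(v)^2, numeric(1))
  n <- vapply(groups, length, numeric(1))
  sqrt(stats::weighted.mean(sd2, n))
}

#' Analyse one continuous-paradigm run
#'
#' Implements the full continuous analysis chain for a single observer run:
#' per-trial report errors; artifact cleaning driven by the matched isolated
#' trial; cosine-similarity tracking performance per condition;
#' flip-and-average; crowding extent by regression intersection (and by
#' hinged fit to the binned noise profile); post-jump windows (uncleaned),
#' exponential decay fits with and without motor-delay correction, and
#' sequential-t-test recovery times.
#'
#' @param traces Tracking traces of one observer run (12 trials by default),
#'   as produced by [generate_dataset()] (`$continuous` filtered to one
#'   observer/run) or read from disk.
#' @param max_distance_deg Largest target-flanker distance, deg.
#' @param window_samples,skip_samples Post-jump window length and
#'   motor-correction skip, in samples.
#' @return A list of class `"continuous_run_analysis"`: `summary` (one-row
#'   tibble), `fits`, `windows` (per condition), `cleaning` (per trial),
#'   `profile` (flanked noise profile).
#' @export
analyze_continuous_run <- function(traces, max_distance_deg = 5,
                                   window_samples = 300, skip_samples = 40) {
  err <- error_series(traces)
  dt <- err$time_s[2] - err$time_s[1]
  trials <- split(err, err$trial)
  info <- tibble::tibble(
    trial = as.integer(names(trials)),
    condition = vapply(trials, function(x) x$condition[1], character(1)),
    trend = vapply(trials, function(x) x$trend[1], character(1))
  )
  iso_ids <- info$trial[info$condition == "isolated"]
  iso_by_trend <- split(info$trial[info$condition == "isolated"],
                        info$trend[info$condition == "isolated"])
  fl_ids <- info$trial[info$condition == "flanked"]
  fl_trends <- stats::setNames(fl_ids, info$trend[info$condition == "flanked"])

  cleaned <- list()
  cleaning <- list()
  # isolated trials: detection on their own series
  for (id in iso_ids) {
    cl <- clean_artifacts(trials[[as.character(id)]], trials[[as.character(id)]])
    cleaned[[as.character(id)]] <- cl$isolated
    cleaning[[length(cleaning) + 1L]] <- tibble::tibble(
      trial = id, condition = "isolated", fraction_removed = cl$thresholds$fraction_removed,
      peak_threshold = cl$thresholds$peak, extend_threshold = cl$thresholds$extend)
  }
  # flanked trials: detection on the matched-trend isolated trial
  partners <- match_isolated_trial(fl_trends, iso_by_trend)
  for (k in seq_along(fl_ids)) {
    id <- fl_ids[k]
    cl <- clean_artifacts(trials[[as.character(partners[k])]], trials[[as.character(id)]])
    cleaned[[as.character(id)]] <- cl$flanked
    cleaning[[length(cleaning) + 1L]] <- tibble::tibble(
      trial = id, condition = "flanked", fraction_removed = cl$thresholds$fraction_removed,
      peak_threshold = cl$thresholds$peak, extend_threshold = cl$thresholds$extend)
  }
  cleaning <- dplyr::bind_rows(cleaning)
  cleaned_all <- dplyr::bind_rows(cleaned)

  # tracking performance on cleaned frames
  cs <- cleaned_all |>
    dplyr::filter(!.data$deleted) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(value = cosine_similarity(.data$target_ori_deg, .data$response_ori_deg),
                     .groups = "drop")
  cs_iso <- cs$value[cs$condition == "isolated"]
  cs_fl <- cs$value[cs$condition == "flanked"]

  # crowding extent: regression intersection on flip-averaged abs errors
  avg_fl <- flip_and_average(cleaned_all[cleaned_all$condition == "flanked", ])
  avg_iso <- flip_and_average(cleaned_all[cleaned_all$condition == "isolated", ])
  fit_fl <- fit_error_vs_distance(avg_fl$abs_error_deg, avg_fl$distance_deg, "flanked")
  fit_iso <- fit_error_vs_distance(avg_iso$abs_error_deg, avg_iso$distance_deg, "isolated")
  ext_int <- crowding_extent_continuous(fit_fl, fit_iso, max_distance_deg)

  # hinged variant on the binned noise profile; frames inside the post-jump
  # reacquisition window measure temporal recovery, not spatial crowding,
  # and are excluded from the profile
  steady <- cleaned_all |>
    dplyr::group_by(.data$trial) |>
    dplyr::mutate(deleted = .data$deleted | post_jump_frames(.data$is_jump, window_samples)) |>
    dplyr::ungroup()
  profile <- noise_profile(steady[steady$condition == "flanked", ])
  baseline_sd <- pooled_noise_sd(steady[steady$condition == "isolated", ])
  hinge <- fit_hinge(profile$distance_deg, profile$circular_sd_deg, baseline_sd,
                     max_h = max_distance_deg, weights = profile$n)
  ext_hinged <- new_crowding_extent(
    min(max(hinge$hinge, 0), max_distance_deg), hinge$hinge,
    "continuous_hinged", hinge, baseline_sd, hinge$status)

  # post-jump recovery (uncleaned errors)
  windows <- list()
  decays <- list()
  recov <- list()
  for (cond in c("isolated", "flanked")) {
    ids <- info$trial[info$condition == cond]
    mats <- purrr::map(ids, function(id) {
      tr <- err[err$trial == id, ]
      extract_post_jump_windows(tr$abs_error_deg, which(tr$is_jump),
                                window_samples = window_samples,
                                skip_samples = 0, dt_s = dt)$window_matrix
    })
    W <- do.call(rbind, mats)
    pjw <- structure(list(window_matrix = W, mean_error = colMeans(W, na.rm = TRUE),
                          time_s = (seq_len(ncol(W)) - 1) * dt, dt_s = dt,
                          skip_samples = 0L),
                     class = "post_jump_windows")
    windows[[cond]] <- pjw
    decays[[paste0(cond, "_uncorrected")]] <-
      fit_exponential_decay(pjw$mean_error, dt, motor_corrected = FALSE)
    keep <- (skip_samples + 1L):ncol(W)
    decays[[paste0(cond, "_corrected")]] <-
      fit_exponential_decay(colMeans(W[, keep, drop = FALSE], na.rm = TRUE), dt,
                            motor_corrected = TRUE, start_time_s = skip_samples * dt)
    recov[[cond]] <- recovery_time(pjw)
  }

  summary <- tibble::tibble(
    cosine_isolated = cs_iso,
    cosine_flanked = cs_fl,
    extent_intersection_deg = ext_int$extent_deg,
    extent_hinged_deg = ext_hinged$extent_deg,
    b_isolated = decays$isolated_uncorrected$b_per_s,
    b_flanked = decays$flanked_uncorrected$b_per_s,
    b_isolated_corrected = decays$isolated_corrected$b_per_s,
    b_flanked_corrected = decays$flanked_corrected$b_per_s,
    c_isolated = decays$isolated_uncorrected$c_deg,
    c_flanked = decays$flanked_uncorrected$c_deg,
    recovery_ms_isolated = recov$isolated$recovery_ms,
    recovery_ms_flanked = recov$flanked$recovery_ms,
    mean_fraction_removed = mean(cleaning$fraction_removed)
  )
  structure(
    list(summary = summary,
         fits = list(flanked = fit_fl, isolated = fit_iso,
                     extent_intersection = ext_int, extent_hinged = ext_hinged,
                     decay = decays, recovery = recov),
         windows = windows, cleaning = cleaning, profile = profile,
         baseline_sd_deg = baseline_sd,
         averaged = list(flanked = avg_fl, isolated = avg_iso)),
    class = "continuous_run_analysis"
  )
}

#' Analyse one trial-based session
#'
#' Von Mises perceptual error per target-flanker distance and crowding
#' extent against the isolated baseline.
#'
#' @param reports Trial-based reports of one observer (`condition`,
#'   `distance_deg`, `target_ori_deg`, `report_ori_deg`).
#' @param max_distance_deg Largest tested distance, deg.
#' @param method Extent estimator, `"intersection"` or `"hinged"`.
#' @return List of class `"trial_based_analysis"`: `summary` (one-row
#'   tibble), `perceptual` (per-distance tibble), `extent`.
#' @export
analyze_trial_based <- function(reports, max_distance_deg = 5,
                                method = c("intersection", "hinged")) {
  method <- match.arg(method)
  reports$error_deg <- report_error(reports$target_ori_deg, reports$report_ori_deg)
  iso <- perceptual_error_vonmises(reports$error_deg[reports$condition == "isolated"])
  fl <- reports[reports$condition == "flanked", ]
  perceptual <- fl |>
    dplyr::group_by(.data$distance_deg) |>
    dplyr::summarise(
      circular_sd_deg = perceptual_error_vonmises(.data$error_deg)$circular_sd_deg,
      kappa = perceptual_error_vonmises(.data$error_deg)$kappa,
      n = dplyr::n(), .groups = "drop")
  extent <- crowding_extent_trial_based(perceptual, iso$circular_sd_deg,
                                        max_distance_deg, method = method)
  structure(
    list(summary = tibble::tibble(extent_deg = extent$extent_deg,
                                  baseline_sd_deg = iso$circular_sd_deg,
                                  method = extent$method),
         perceptual = perceptual, baseline = iso, extent = extent),
    class = "trial_based_analysis"
  )
}

#' Analyse a full dataset
#'
#' Runs the continuous analysis per observer and run, the trial-based
#' analysis per observer, and the group-level statistics: a 2x2
#' repeated-measures ANOVA (flank condition x run) on tracking performance
#' and on recovery rate (with and without motor correction), paired t-tests
#' on crowding extents (run 1 vs run 2; continuous mean vs trial-based), the
#' cross-paradigm Pearson correlation, and recovery times pooled across
#' participants.
#'
#' @param dataset A `"crowding_dataset"` from [generate_dataset()] or
#'   [read_dataset()].
#' @param extent_method Extent estimator used for the group comparisons:
#'   `"intersection"` (regression/baseline crossing) or `"hinged"`.
#' @return A list of class `"crowding_analysis"`: `runs` (per observer x run
#'   tibble), `trial_based` (per observer tibble), `group` (list of test
#'   results), `pooled_recovery` (per condition), `details`.
#' @export
analyze_dataset <- function(dataset, extent_method = c("intersection", "hinged")) {
  extent_method <- match.arg(extent_method)
  cfg <- dataset$config
  max_d <- cfg$distance_max_deg
  keys <- dplyr::distinct(dataset$continuous[, c("observer", "run")])
  run_results <- purrr::pmap(keys, function(observer, run) {
    tr <- dataset$continuous[dataset$continuous$observer == observer &
                               dataset$continuous$run == run, ]
    res <- analyze_continuous_run(tr, max_distance_deg = max_d)
    res$summary$observer <- observer
    res$summary$run <- run
    res
  })
  runs <- dplyr::bind_rows(purrr::map(run_results, "summary"))
  runs$extent_deg <- if (extent_method == "hinged") runs$extent_hinged_deg else runs$extent_intersection_deg

  tb_results <- purrr::map(sort(unique(dataset$trial_based$observer)), function(oi) {
    res <- analyze_trial_based(dataset$trial_based[dataset$trial_based$observer == oi, ],
                               max_distance_deg = max_d, method = extent_method)
    res$summary$observer <- oi
    res
  })
  tb <- dplyr::bind_rows(purrr::map(tb_results, "summary"))

  group <- list()
  n_obs <- length(unique(runs$observer))
  two_runs <- length(unique(runs$run)) >= 2
  if (n_obs >= 2 && two_runs) {
    long <- runs |>
      dplyr::select("observer", "run", "cosine_isolated", "cosine_flanked") |>
      tidyr::pivot_longer(c("cosine_isolated", "cosine_flanked"),
                          names_to = "condition", names_prefix = "cosine_",
                          values_to = "value")
    group$anova_tracking <- rm_anova_2x2(long, "value", "observer", "condition", "run")
    for (suffix in c("", "_corrected")) {
      longb <- runs |>
        dplyr::select("observer", "run",
                      iso = dplyr::all_of(paste0("b_isolated", suffix)),
                      fl = dplyr::all_of(paste0("b_flanked", suffix))) |>
        tidyr::pivot_longer(c("iso", "fl"), names_to = "condition", values_to = "value")
      group[[paste0("anova_recovery_rate", suffix)]] <-
        rm_anova_2x2(longb, "value", "observer", "condition", "run")
    }
    wide_ext <- runs |>
      dplyr::select("observer", "run", "extent_deg") |>
      tidyr::pivot_wider(names_from = "run", values_from = "extent_deg",
                         names_prefix = "run")
    group$t_extent_runs <- tryCatch(paired_t(wide_ext$run1, wide_ext$run2),
                                    error = function(e) NULL)
    cont_mean <- runs |>
      dplyr::group_by(.data$observer) |>
      dplyr::summarise(extent_continuous = mean(.data$extent_deg), .groups = "drop") |>
      dplyr::left_join(tb[, c("observer", "extent_deg")], by = "observer") |>
      dplyr::rename(extent_trial_based = "extent_deg")
    group$t_extent_paradigms <- tryCatch(
      paired_t(cont_mean$extent_continuous, cont_mean$extent_trial_based),
      error = function(e) NULL)
    group$r_extent_paradigms <- tryCatch(
      pearson_r(cont_mean$extent_continuous, cont_mean$extent_trial_based),
      error = function(e) NULL)
    group$extents <- cont_mean
  }

  pooled_recovery <- list()
  for (cond in c("isolated", "flanked")) {
    W <- do.call(rbind, purrr::map(run_results, function(r) r$windows[[cond]]$window_matrix))
    dt <- run_results[[1]]$windows[[cond]]$dt_s
    pjw <- structure(list(window_matrix = W, mean_error = colMeans(W, na.rm = TRUE),
                          time_s = (seq_len(ncol(W)) - 1) * dt, dt_s = dt,
                          skip_samples = 0L),
                     class = "post_jump_windows")
    pooled_recovery[[cond]] <- recovery_time(pjw)
  }

  structure(
    list(runs = runs, trial_based = tb, group = group,
         pooled_recovery = pooled_recovery,
         details = list(runs = run_results, trial_based = tb_results),
         extent_method = extent_method),
    class = "crowding_analysis"
  )
}

#' @export
print.crowding_analysis <- function(x, ...) {
  cat("Crowding analysis\n")
  cat(sprintf("  observers: %d, continuous runs: %d\n",
              length(unique(x$runs$observer)), nrow(x$runs)))
  cat(sprintf("  tracking performance: isolated %.3f, flanked %.3f (means)\n",
              mean(x$runs$cosine_isolated), mean(x$runs$cosine_flanked)))
  cat(sprintf("  crowding extent (%s): continuous %.2f deg, trial-based %.2f deg (means)\n",
              x$extent_method, mean(x$runs$extent_deg), mean(x$trial_based$extent_deg)))
  cat(sprintf("  recovery rate b: isolated %.2f /s, flanked %.2f /s (means)\n",
              mean(x$runs$b_isolated), mean(x$runs$b_flanked)))
  cat(sprintf("  pooled recovery time: isolated %.0f ms, flanked %.0f ms\n",
              x$pooled_recovery$isolated$recovery_ms,
              x$pooled_recovery$flanked$recovery_ms))
  invisible(x)
}

#' @method glance crowding_analysis
#' @export
glance.crowding_analysis <- function(x, ...) {
  tibble::tibble(
    n_observers = length(unique(x$runs$observer)),
    cosine_isolated = mean(x$runs$cosine_isolated),
    cosine_flanked = mean(x$runs$cosine_flanked),
    extent_continuous_deg = mean(x$runs$extent_deg),
    extent_trial_based_deg = mean(x$trial_based$extent_deg),
    b_isolated = mean(x$runs$b_isolated),
    b_flanked = mean(x$runs$b_flanked),
    recovery_ms_isolated = x$pooled_recovery$isolated$recovery_ms,
    recovery_ms_flanked = x$pooled_recovery$flanked$recovery_ms,
    mean_fraction_removed = mean(x$runs$mean_fraction_removed)
  )
}
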