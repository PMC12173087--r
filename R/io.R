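# File-based runs: dataset CSV export/import, run manifests, and the
# simulate / analyze / recover entry points.

#' Write a synthetic dataset to disk
#'
#' One directory per observer (`obs01/`, ...) with `continuous.csv` and
#' `trial_based.csv`, plus the paradigm/observer configuration
#' (`config.yaml`) and a run manifest (`manifest.json`) with MD5 hashes of
#' every file written.
#'
#' @param dataset A `"crowding_dataset"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (oi in sort(unique(dataset$continuous$observer))) {
    od <- file.path(dir, sprintf("obs%02d", oi))
    dir.create(od, showWarnings = FALSE)
    cont <- dataset$continuous[dataset$continuous$observer == oi, ]
    cont <- dplyr::rename(cont, trial_id = "trial")
    readr::write_csv(cont[, c("run", "trial_id", "frame", "time_s", "condition",
                              "trend", "target_ori_deg", "response_ori_deg",
                              "distance_deg", "direction", "is_jump", "gap_mask")],
                     file.path(od, "continuous.csv"))
    tb <- dataset$trial_based[dataset$trial_based$observer == oi, ]
    tb <- dplyr::rename(tb, trial_id = "trial")
    readr::write_csv(tb[, c("trial_id", "condition", "distance_deg",
                            "target_ori_deg", "report_ori_deg")],
                     file.path(od, "trial_based.csv"))
    files <- c(files, file.path(od, "continuous.csv"), file.path(od, "trial_based.csv"))
  }
  write_config(dataset$config, dataset$observers, file.path(dir, "config.yaml"))
  files <- c(files, file.path(dir, "config.yaml"))
  manifest <- list(
    created = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("crowdtrack")),
    seed = dataset$seed,
    n_observers = length(unique(dataset$continuous$observer)),
    n_runs = dataset$n_runs,
    files = lapply(files, function(f) {
      list(path = sub(paste0("^", dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @param verify Check the manifest MD5 hashes and stop on mismatch.
#' @return A `"crowding_dataset"`.
#' @export
read_dataset <- function(dir, verify = TRUE) {
  man_path <- file.path(dir, "manifest.json")
  if (verify && file.exists(man_path)) {
    man <- jsonlite::read_json(man_path)
    for (f in man$files) {
      p <- file.path(dir, f$path)
      if (!file.exists(p)) stop("read_dataset(): missing file ", p, call. = FALSE)
      if (unname(tools::md5sum(p)) != f$md5) {
        stop("read_dataset(): hash mismatch for ", p, call. = FALSE)
      }
    }
  }
  cfgs <- read_config(file.path(dir, "config.yaml"))
  dirs <- sort(list.dirs(dir, recursive = FALSE))
  dirs <- dirs[grepl("obs[0-9]+$", dirs)]
  cont <- list(); tb <- list()
  spec_cont <- readr::cols(
    run = readr::col_integer(), trial_id = readr::col_integer(),
    frame = readr::col_integer(), time_s = readr::col_double(),
    condition = readr::col_character(), trend = readr::col_character(),
    target_ori_deg = readr::col_double(), response_ori_deg = readr::col_double(),
    distance_deg = readr::col_double(), direction = readr::col_integer(),
    is_jump = readr::col_logical(), gap_mask = readr::col_logical()
  )
  for (k in seq_along(dirs)) {
    oi <- as.integer(sub(".*obs", "", dirs[k]))
    x <- readr::read_csv(file.path(dirs[k], "continuous.csv"),
                         col_types = spec_cont, progress = FALSE)
    check_columns(x, c("run", "trial_id", "frame", "time_s", "condition", "trend",
                       "target_ori_deg", "response_ori_deg", "distance_deg"),
                  file.path(dirs[k], "continuous.csv"))
    x$observer <- oi
    cont[[k]] <- dplyr::rename(x, trial = "trial_id")
    y <- readr::read_csv(file.path(dirs[k], "trial_based.csv"),
                         col_types = readr::cols(), progress = FALSE)
    check_columns(y, c("trial_id", "condition", "distance_deg",
                       "target_ori_deg", "report_ori_deg"),
                  file.path(dirs[k], "trial_based.csv"))
    y$observer <- oi
    tb[[k]] <- dplyr::rename(y, trial = "trial_id")
  }
  structure(
    list(continuous = dplyr::bind_rows(cont), trial_based = dplyr::bind_rows(tb),
         config = cfgs$paradigm, observers = cfgs$observers,
         n_runs = max(purrr::map_int(cont, ~ max(.x$run))), seed = NA_integer_),
    class = "crowding_dataset"
  )
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  invisible(df)
}

#' Simulate a dataset to disk
#'
#' Generates a synthetic multi-observer dataset under the given paradigm and
#' observer configurations and writes it with [write_dataset()].
#'
#' @param config A [paradigm_config()], or a path to a YAML/JSON config file
#'   (which may also define the observers).
#' @param out_dir Output directory.
#' @param seed Root seed.
#' @param n_observers Number of synthetic observers when the config does not
#'   define them individually (they then share the default observer model,
#'   with per-observer seeds).
#' @param n_runs Continuous runs per observer.
#' @return The dataset, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = 1L, n_observers = 8, n_runs = 2) {
  if (is.character(config)) {
    cfgs <- read_config(config)
    paradigm <- cfgs$paradigm
    observers <- cfgs$observers
  } else {
    paradigm <- config
    observers <- list(observer_config())
  }
  if (length(observers) == 1L && n_observers > 1L) {
    proto <- observers[[1]]
    observers <- lapply(seq_len(n_observers), function(i) {
      o <- proto
      o$seed <- derive_seed(seed, 23L, i)
      o
    })
  }
  ds <- generate_dataset(paradigm, observers, n_runs = n_runs, seed = seed)
  write_dataset(ds, out_dir)
  invisible(ds)
}

#' Analyse a dataset directory
#'
#' Reads a dataset written by [run_simulate()]/[write_dataset()], runs
#' [analyze_dataset()], and writes per-participant results
#' (`results_obsNN.json`), a group report (`group.json`) and a cleaning
#' report (`cleaning.json`).
#'
#' @param data_dir Dataset directory.
#' @param out_dir Output directory for result JSON files.
#' @param extent_method Passed to [analyze_dataset()].
#' @return The `"crowding_analysis"`, invisibly.
#' @export
run_analyze <- function(data_dir, out_dir, extent_method = "intersection") {
  ds <- read_dataset(data_dir)
  res <- analyze_dataset(ds, extent_method = extent_method)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (oi in sort(unique(res$runs$observer))) {
    rr <- res$runs[res$runs$observer == oi, ]
    tbr <- res$trial_based[res$trial_based$observer == oi, ]
    out <- list(
      schema_version = "1.0",
      observer = oi,
      tracking_performance = lapply(split(rr, rr$run), function(r) {
        list(isolated = r$cosine_isolated, flanked = r$cosine_flanked)
      }),
      crowding_extent = list(
        continuous_runs = rr$extent_deg,
        continuous_mean = mean(rr$extent_deg),
        trial_based = tbr$extent_deg
      ),
      decay = lapply(split(rr, rr$run), function(r) {
        list(isolated = list(uncorrected = r$b_isolated, corrected = r$b_isolated_corrected),
             flanked = list(uncorrected = r$b_flanked, corrected = r$b_flanked_corrected))
      }),
      recovery_time_ms = lapply(split(rr, rr$run), function(r) {
        list(isolated = r$recovery_ms_isolated, flanked = r$recovery_ms_flanked)
      })
    )
    jsonlite::write_json(out, file.path(out_dir, sprintf("results_obs%02d.json", oi)),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  group <- list(schema_version = "1.0")
  for (nm in names(res$group)) {
    g <- res$group[[nm]]
    group[[nm]] <- if (inherits(g, "rm_anova")) {
      as.list(tidy(g))
    } else if (is.data.frame(g)) {
      as.list(g)
    } else g
  }
  group$pooled_recovery_ms <- list(
    isolated = res$pooled_recovery$isolated$recovery_ms,
    flanked = res$pooled_recovery$flanked$recovery_ms
  )
  jsonlite::write_json(group, file.path(out_dir, "group.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cleaning <- purrr::imap(res$details$runs, function(r, i) {
    cbind(observer = r$summary$observer, run = r$summary$run, r$cleaning)
  })
  jsonlite::write_json(list(schema_version = "1.0",
                            per_trial = dplyr::bind_rows(cleaning)),
                       file.path(out_dir, "cleaning.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Parameter-recovery study
#'
#' For each true value in `grid`, simulates a multi-observer dataset whose
#' observers carry that value, runs the full analysis, and tabulates
#' estimates against truth.
#'
#' @param param `"crowding_extent_deg"` (recovers spatial extent with both
#'   paradigms' hinged estimators) or `"recovery_rate"` (recovers the
#'   exponential decay rate from post-jump windows).
#' @param grid True parameter values.
#' @param config A [paradigm_config()].
#' @param n_observers,n_runs Dataset size per grid point.
#' @param seed Root seed.
#' @param out_dir Optional directory; when given, the table is written to
#'   `recovery.csv` there.
#' @return A tibble with one row per grid point x observer (extent) or per
#'   grid point (rate): truth, estimates, bias.
#' @export
run_recover <- function(param = c("crowding_extent_deg", "recovery_rate"),
                        grid, config = paradigm_config(), n_observers = 8,
                        n_runs = 2, seed = 1L, out_dir = NULL) {
  param <- match.arg(param)
  rows <- list()
  if (param == "crowding_extent_deg") {
    for (g in seq_along(grid)) {
      ec <- grid[g]
      observers <- lapply(seq_len(n_observers), function(i) {
        observer_config(crowding_extent_deg = ec, seed = derive_seed(seed, g, i))
      })
      ds <- generate_dataset(config, observers, n_runs = n_runs,
                             seed = derive_seed(seed, 31L, g))
      res <- analyze_dataset(ds, extent_method = "hinged")
      cont <- res$runs |>
        dplyr::group_by(.data$observer) |>
        dplyr::summarise(extent_continuous = mean(.data$extent_deg),
                         extent_intersection = mean(.data$extent_intersection_deg),
                         .groups = "drop")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        true_value = ec,
        observer = cont$observer,
        extent_continuous = cont$extent_continuous,
        extent_intersection = cont$extent_intersection,
        extent_trial_based = res$trial_based$extent_deg
      )
    }
    out <- dplyr::bind_rows(rows)
    out$bias_continuous <- out$extent_continuous - out$true_value
    out$bias_trial_based <- out$extent_trial_based - out$true_value
  } else {
    for (g in seq_along(grid)) {
      rate <- grid[g]
      obs <- observer_config(recovery_rate_flanked_per_s = rate,
                             recovery_rate_isolated_per_s = rate,
                             seed = derive_seed(seed, 41L, g))
      fit <- recover_decay_rate(obs, config, n_trials = 10,
                                seed = derive_seed(seed, 43L, g))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        true_value = rate, b_hat = fit$b_per_s,
        bias = fit$b_per_s - rate, rel_error = (fit$b_per_s - rate) / rate
      )
    }
    out <- dplyr::bind_rows(rows)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out, file.path(out_dir, "recovery.csv"))
  }
  out
}

# Simulate isolated trials for one observer (the condition with the lowest
# error floor), pool post-jump windows and fit the motor-corrected decay.
# 10 trials x 5 jumps = 50 jumps by default.
recover_decay_rate <- function(observer, config = paradigm_config(),
                               n_trials = 10, seed = 1L, skip_samples = 40) {
  mats <- purrr::map(seq_len(n_trials), function(i) {
    stim <- generate_continuous_trial(config, "isolated",
                                      trend = if (i %% 2) "increasing" else "decreasing",
                                      seed = derive_seed(seed, i))
    tr <- error_series(simulate_tracking_response(stim, observer,
                                                  seed = derive_seed(seed, i, 3L)))
    extract_post_jump_windows(tr$abs_error_deg, which(tr$is_jump),
                              skip_samples = skip_samples,
                              dt_s = 1 / config$sample_rate_hz)$window_matrix
  })
  W <- do.call(rbind, mats)
  fit_exponential_decay(colMeans(W, na.rm = TRUE), 1 / config$sample_rate_hz,
                        motor_corrected = TRUE,
                        start_time_s = skip_samples / config$sample_rate_hz)
}
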