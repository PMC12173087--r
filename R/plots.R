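#' @import ggplot2
#' @importFrom rlang .data
NULL

#' Plot report error versus target-flanker distance
#'
#' Flip-averaged absolute report error for both conditions with the fitted
#' regression lines and the estimated crowding extent.
#'
#' @param x A `"continuous_run_analysis"` from [analyze_continuous_run()].
#' @param bin_width_deg Distance bin width used for display averaging.
#' @return A ggplot object.
#' @export
plot_error_vs_distance <- function(x, bin_width_deg = 0.1) {
  df <- dplyr::bind_rows(
    dplyr::mutate(x$averaged$flanked, condition = "flanked"),
    dplyr::mutate(x$averaged$isolated, condition = "isolated")
  ) |>
    dplyr::mutate(bin = floor(.data$distance_deg / bin_width_deg)) |>
    dplyr::group_by(.data$condition, .data$bin) |>
    dplyr::summarise(distance_deg = mean(.data$distance_deg),
                     abs_error_deg = mean(.data$abs_error_deg, na.rm = TRUE),
                     .groups = "drop")
  lines <- tibble::tibble(
    condition = c("flanked", "isolated"),
    slope = c(x$fits$flanked$slope, x$fits$isolated$slope),
    intercept = c(x$fits$flanked$intercept, x$fits$isolated$intercept)
  )
  ext <- x$fits$extent_intersection$extent_deg
  ggplot(df, aes(x = .data$distance_deg, y = .data$abs_error_deg,
                 colour = .data$condition)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_abline(data = lines,
                aes(slope = .data$slope, intercept = .data$intercept,
                    colour = .data$condition)) +
    geom_vline(xintercept = ext, linetype = "dashed") +
    scale_colour_manual(values = c(flanked = "#c0392b", isolated = "#2e6da4")) +
    labs(x = "Target-flanker distance (deg)", y = "Absolute report error (deg)",
         colour = NULL,
         subtitle = sprintf("Crowding extent (intersection): %.2f deg", ext)) +
    theme_minimal()
}

#' Plot a post-jump decay fit
#'
#' Mean absolute report error after the jumps with the fitted exponential
#' decay curve.
#'
#' @param object A `"decay_fit"`.
#' @param data Optional [extract_post_jump_windows()] result providing the
#'   raw mean-error samples; when omitted only the fitted curve is drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, data = NULL, ...) {
  df <- tibble::tibble(time_s = object$time_s, fitted = object$fitted)
  p <- ggplot(df, aes(x = .data$time_s))
  if (!is.null(data)) {
    raw <- tibble::tibble(time_s = data$time_s, mean_error = data$mean_error)
    p <- p + geom_line(data = raw, aes(y = .data$mean_error), colour = "grey30")
  }
  p +
    geom_line(aes(y = .data$fitted), colour = "#c0392b", linewidth = 1) +
    labs(x = "Time after jump (s)", y = "Mean absolute report error (deg)",
         subtitle = sprintf("E(t) = %.1f exp(-%.2f t) + %.1f%s",
                            object$a_deg, object$b_per_s, object$c_deg,
                            if (object$motor_corrected) "  (motor-corrected)" else "")) +
    theme_minimal()
}

#' Plot a perceptual-error profile with its hinged fit
#'
#' Perceptual error (circular SD) per target-flanker distance, the isolated
#' baseline, and the estimated crowding extent.
#'
#' @param perceptual Tibble with `distance_deg`, `circular_sd_deg`.
#' @param baseline_sd_deg Isolated baseline, deg.
#' @param extent A `"crowding_extent"` (optional).
#' @return A ggplot object.
#' @export
plot_noise_profile <- function(perceptual, baseline_sd_deg, extent = NULL) {
  p <- ggplot(perceptual, aes(x = .data$distance_deg, y = .data$circular_sd_deg)) +
    geom_point(colour = "#c0392b") +
    geom_hline(yintercept = baseline_sd_deg, linetype = "dashed", colour = "#2e6da4") +
    labs(x = "Target-flanker distance (deg)", y = "Perceptual error (deg)") +
    theme_minimal()
  if (!is.null(extent)) {
    p <- p + geom_vline(xintercept = extent$extent_deg, linetype = "dotted") +
      labs(subtitle = sprintf("Crowding extent: %.2f deg (%s)",
                              extent$extent_deg, extent$method))
  }
  p
}
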