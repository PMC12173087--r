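# Group-level inference: paired t-tests, 2x2 repeated-measures ANOVA with
# partial eta squared, Pearson correlation.

#' Paired-samples t-test with Cohen's d
#'
#' @param x,y Per-subject values, equal length.
#' @return A tibble: `t`, `df`, `p`, `cohen_d`, `mean_diff`, `n`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("paired_t(): zero-variance differences", call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    cohen_d = mean(d) / stats::sd(d), mean_diff = mean(d), n = length(x)
  )
}

#' 2x2 repeated-measures ANOVA
#'
#' Fully within-subject two-factor design. Sums of squares are computed from
#' cell, marginal and subject means; each effect is tested against its own
#' subject-by-effect interaction with `F(1, n - 1)`. Effect size is partial
#' eta squared, `SS_effect / (SS_effect + SS_error_effect)`.
#'
#' @param data Data frame with one row per subject x cell.
#' @param value,subject,factor_a,factor_b Column names (strings).
#' @return An object of class `"rm_anova"`: tibble with one row per effect
#'   (`A`, `B`, `A:B`): `effect`, `F`, `df_num`, `df_den`, `p`,
#'   `partial_eta_sq`.
#' @export
rm_anova_2x2 <- function(data, value, subject, factor_a, factor_b) {
  y <- data[[value]]
  s <- factor(data[[subject]])
  a <- factor(data[[factor_a]])
  b <- factor(data[[factor_b]])
  if (nlevels(a) != 2L || nlevels(b) != 2L) {
    stop("rm_anova_2x2(): both factors must have exactly 2 levels", call. = FALSE)
  }
  n <- nlevels(s)
  if (n < 2L) stop("rm_anova_2x2(): need >= 2 subjects", call. = FALSE)
  counts <- table(s, a, b)
  if (any(counts != 1L)) {
    stop("rm_anova_2x2(): design must be complete with one observation per cell",
         call. = FALSE)
  }
  gm <- mean(y)
  m_s <- tapply(y, s, mean)
  m_a <- tapply(y, a, mean)
  m_b <- tapply(y, b, mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_sa <- tapply(y, list(s, a), mean)
  m_sb <- tapply(y, list(s, b), mean)

  ss_a <- 2 * n * sum((m_a - gm)^2)
  ss_b <- 2 * n * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a - gm, m_b - gm, "+") - gm)^2)
  ss_sa <- 2 * sum((m_sa - outer(m_s - gm, m_a - gm, "+") - gm)^2)
  ss_sb <- 2 * sum((m_sb - outer(m_s - gm, m_b - gm, "+") - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_subj <- 4 * sum((m_s - gm)^2)
  ss_sab <- ss_tot - ss_subj - ss_a - ss_b - ss_ab - ss_sa - ss_sb

  effect_row <- function(name, ss_eff, ss_err) {
    df_den <- n - 1
    ms_eff <- ss_eff / 1
    ms_err <- ss_err / df_den
    f <- if (ms_err <= 0) Inf else ms_eff / ms_err
    tibble::tibble(
      effect = name, F = f, df_num = 1, df_den = df_den,
      p = stats::pf(f, 1, df_den, lower.tail = FALSE),
      partial_eta_sq = if (ss_eff + ss_err <= 0) 0 else ss_eff / (ss_eff + ss_err)
    )
  }
  out <- dplyr::bind_rows(
    effect_row("A", ss_a, ss_sa),
    effect_row("B", ss_b, ss_sb),
    effect_row("A:B", ss_ab, ss_sab)
  )
  out$factor_a <- factor_a
  out$factor_b <- factor_b
  class(out) <- c("rm_anova", class(out))
  out
}

#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::as_tibble(x)[, c("effect", "F", "df_num", "df_den", "p", "partial_eta_sq")]
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return A tibble: `r`, `df`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("pearson_r(): need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r(): zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value, n = length(x))
}
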