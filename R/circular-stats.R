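#' Wrap orientations to \[0, 360)
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector in `[0, 360)`.
#' @export
#' @examples
#' wrap_360(c(-10, 370, 360))
wrap_360 <- function(x) {
  x %% 360
}

#' Wrap signed angular differences to \[-180, 180)
#'
#' The half-open convention resolves the tie at the antipode to -180.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector in `[-180, 180)`.
#' @export
#' @examples
#' wrap_180(c(180, -180, 190, 350))
wrap_180 <- function(x) {
  ((x + 180) %% 360) - 180
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular mean and resultant length
#'
#' @param x Angles in degrees.
#' @param na.rm Drop missing values first?
#' @return A list with `mean_deg` (in `[0, 360)`), `rbar` (mean resultant
#'   length in `[0, 1]`) and `n`.
#' @export
circ_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop("circ_mean(): no data", call. = FALSE)
  r <- deg2rad(x)
  s <- sum(sin(r)) / n
  c_ <- sum(cos(r)) / n
  list(mean_deg = wrap_360(rad2deg(atan2(s, c_))), rbar = sqrt(s^2 + c_^2), n = n)
}

#' Circular standard deviation
#'
#' Uses the standard definition `sqrt(-2 log(Rbar))`, returned in degrees.
#'
#' @inheritParams circ_mean
#' @return Circular SD in degrees (0 for perfectly concentrated data).
#' @export
circ_sd <- function(x, na.rm = FALSE) {
  m <- circ_mean(x, na.rm = na.rm)
  rbar <- min(m$rbar, 1)
  if (rbar <= 0) return(Inf)
  rad2deg(sqrt(-2 * log(rbar)))
}

# Ratio of modified Bessel functions I1/I0; the mean resultant length of a
# Von Mises distribution with concentration kappa. Scaled Bessels avoid
# overflow for large kappa.
besselI_ratio <- function(kappa) {
  ifelse(kappa == 0, 0,
    besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
  )
}

# Inverse of besselI_ratio by monotone root finding.
a1inv <- function(rbar) {
  if (rbar <= 0) return(0)
  if (rbar >= 1) return(Inf)
  # Banerjee et al. starting bracket around the standard approximation
  k0 <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  lo <- max(k0 / 4, 1e-8)
  hi <- max(k0 * 4, 1)
  while (besselI_ratio(hi) < rbar && hi < 1e12) hi <- hi * 4
  if (besselI_ratio(hi) < rbar) return(Inf)
  stats::uniroot(function(k) besselI_ratio(k) - rbar, c(lo, hi), tol = 1e-10)$root
}

#' Draw from a Von Mises distribution
#'
#' Best-Fisher rejection sampler; degrees in, degrees out.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction in degrees.
#' @param kappa Concentration (>= 0). `kappa = 0` is the circular uniform;
#'   `kappa = Inf` returns `mu_deg` exactly.
#' @return Numeric vector of angles in `[0, 360)`.
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (!is.finite(kappa)) return(rep(wrap_360(mu_deg), n))
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- deg2rad(mu_deg)
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    m <- n - i + 1L
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    f <- f[ok]
    if (length(f)) {
      u3 <- stats::runif(length(f))
      theta <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
      take <- seq_len(min(length(theta), n - i + 1L))
      out[i + take - 1L] <- theta[take]
      i <- i + length(take)
    }
  }
  wrap_360(rad2deg(mu + out))
}

#' Maximum-likelihood Von Mises fit
#'
#' Fits mean direction and concentration by maximum likelihood (the MLE of
#' kappa solves `I1(k)/I0(k) = Rbar`). All-identical input is the degenerate
#' point mass: `kappa = Inf`, circular SD 0.
#'
#' @param x Angles in degrees (e.g. signed report errors).
#' @return An object of class `"vm_fit"`: list with `mu_deg`, `kappa`,
#'   `rbar`, `circular_sd_deg` and `n`.
#' @export
fit_vonmises <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 1L) stop("fit_vonmises(): no data", call. = FALSE)
  m <- circ_mean(x)
  kappa <- a1inv(m$rbar)
  # circular SD implied by the fitted concentration
  rbar_hat <- if (is.finite(kappa)) besselI_ratio(kappa) else 1
  sd_deg <- if (rbar_hat >= 1) 0 else rad2deg(sqrt(-2 * log(rbar_hat)))
  structure(
    list(mu_deg = m$mean_deg, kappa = kappa, rbar = m$rbar,
         circular_sd_deg = sd_deg, n = n),
    class = "vm_fit"
  )
}

#' @export
print.vm_fit <- function(x, ...) {
  cat(sprintf("Von Mises fit: mu = %.2f deg, kappa = %.3f, circular SD = %.2f deg (n = %d)\n",
              x$mu_deg, x$kappa, x$circular_sd_deg, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy vm_fit
#' @export
tidy.vm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mu_deg", "kappa", "circular_sd_deg"),
    estimate = c(x$mu_deg, x$kappa, x$circular_sd_deg)
  )
}

#' @method glance vm_fit
#' @export
glance.vm_fit <- function(x, ...) {
  tibble::tibble(mu_deg = x$mu_deg, kappa = x$kappa,
                 circular_sd_deg = x$circular_sd_deg, n = x$n)
}
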