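#' Von Mises turning-angle distribution
#'
#' Density, cumulative mass along the real line, arc masses, random deviates
#' and maximum-likelihood concentration estimation for the von Mises
#' distribution with mean direction 0,
#' \deqn{p(\theta) = \frac{1}{2\pi I_0(\kappa)} e^{\kappa \cos\theta},}
#' the null model for the turning angles of a directionally persistent but
#' target-blind cell.  \eqn{\kappa = 0} is the uniform (non-persistent)
#' limit; large \eqn{\kappa} means nearly straight migration.
#'
#' `vonmises_arc_mass()` integrates the density over an arbitrary arc
#' \eqn{[a, b]} of the circle.  The endpoints are understood as points on the
#' real line (the universal cover), so arcs may cross the \eqn{\pm\pi} branch
#' cut; an arc of total length \eqn{2\pi} has mass exactly 1.  Internally the
#' mass is evaluated through the Fourier series of the cumulative function,
#' \deqn{F(x) = \frac{x}{2\pi} + \frac{1}{\pi}\sum_{j\ge1}
#'       \frac{I_j(\kappa)}{I_0(\kappa)} \frac{\sin(j x)}{j},}
#' truncated when the Bessel-function ratio falls below `1e-14`, which is
#' far below the documented absolute accuracy of 1e-10.
#'
#' @param theta,x angles in radians (any real value).
#' @param kappa concentration parameter, \eqn{\kappa \ge 0}.
#' @param a,b arc endpoints in radians with `a <= b`; `b - a` may exceed
#'   \eqn{2\pi}, in which case the mass is 1.
#' @param n number of deviates to draw; `kappa` and `mu` are recycled to
#'   length `n`.
#' @param mu mean direction(s) in radians for `rvonmises()`.
#' @return `dvonmises()` and `vonmises_arc_mass()` return numeric vectors;
#'   `rvonmises()` returns `n` angles wrapped to \eqn{(-\pi, \pi]}.
#' @examples
#' vonmises_arc_mass(2, -pi, pi)        # full circle: 1
#' vonmises_arc_mass(0, 0, pi / 2)      # uniform limit: 1/4
#' @name vonmises
NULL

# Fourier coefficients a_j = I_j(kappa) / I_0(kappa), truncated at tol.
# Scaled Bessel functions keep the ratio finite for large kappa.
vm_fourier_coeffs <- function(kappa, tol = 1e-14, jmax = 3000L) {
  if (kappa <= 0) return(numeric(0))
  i0 <- besselI(kappa, 0, expon.scaled = TRUE)
  out <- numeric(64L)
  j <- 0L
  repeat {
    j <- j + 1L
    aj <- besselI(kappa, j, expon.scaled = TRUE) / i0
    if (j > length(out)) out <- c(out, numeric(length(out)))
    out[j] <- aj
    if (aj < tol || j >= jmax) break
  }
  out[seq_len(j)]
}

# Cumulative mass F(x) = integral of the density from 0 to x, for any real x.
# Vectorized over x; coeffs may be precomputed with vm_fourier_coeffs().
vm_cummass <- function(x, kappa, coeffs = NULL) {
  if (kappa < 0) stop("kappa must be non-negative")
  if (is.null(coeffs)) coeffs <- vm_fourier_coeffs(kappa)
  f <- x / (2 * pi)
  if (length(coeffs)) {
    j <- seq_along(coeffs)
    # outer(x, j) can be large; chunk to bound memory for very long inputs
    n <- length(x)
    chunk <- max(1L, 2e6L %/% length(j))
    for (s in seq(1L, n, by = chunk)) {
      idx <- s:min(n, s + chunk - 1L)
      f[idx] <- f[idx] + sin(outer(x[idx], j)) %*% (coeffs / j) / pi
    }
  }
  as.numeric(f)
}

#' @rdname vonmises
#' @export
dvonmises <- function(theta, kappa) {
  stopifnot(kappa >= 0)
  # exp(kappa * (cos(theta) - 1)) / (2 pi I0(kappa) e^-kappa): stable for large kappa
  exp(kappa * (cos(theta) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' @rdname vonmises
#' @export
vonmises_arc_mass <- function(kappa, a, b) {
  stopifnot(kappa >= 0, length(a) == length(b) || length(a) == 1L || length(b) == 1L)
  if (any(b < a)) stop("arc endpoints must satisfy a <= b")
  coeffs <- vm_fourier_coeffs(kappa)
  m <- vm_cummass(b, kappa, coeffs) - vm_cummass(a, kappa, coeffs)
  m[(b - a) >= 2 * pi] <- 1
  pmin(pmax(m, 0), 1)
}

#' @rdname vonmises
#' @export
rvonmises <- function(n, kappa, mu = 0) {
  stopifnot(n >= 0, all(kappa >= 0))
  kappa <- rep_len(kappa, n)
  mu <- rep_len(mu, n)
  theta <- numeric(n)
  unif <- kappa < 1e-9
  if (any(unif)) theta[unif] <- stats::runif(sum(unif), -pi, pi)
  todo <- which(!unif)
  if (length(todo)) {
    # Best & Fisher (1979) wrapped-Cauchy envelope rejection sampler
    k <- kappa[todo]
    tau <- 1 + sqrt(1 + 4 * k^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * k)
    rpar <- (1 + rho^2) / (2 * rho)
    dev <- numeric(length(todo))
    pending <- seq_along(todo)
    while (length(pending)) {
      m <- length(pending)
      u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + rpar[pending] * z) / (rpar[pending] + z)
      cc <- k[pending] * (rpar[pending] - f)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      dev[pending[ok]] <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      pending <- pending[!ok]
    }
    theta[todo] <- dev
  }
  wrap_angle(theta + mu)
}

# Map angles to (-pi, pi].
wrap_angle <- function(x) {
  w <- x %% (2 * pi)
  gt <- !is.na(w) & w > pi
  w[gt] <- w[gt] - 2 * pi
  w
}

#' Estimate the von Mises concentration parameter
#'
#' Maximum-likelihood estimate of \eqn{\kappa} for turning angles with mean
#' direction fixed at 0: \eqn{\hat\kappa} solves
#' \eqn{I_1(\kappa)/I_0(\kappa) = \overline{\cos\theta}}.  A non-positive
#' mean cosine (anti-persistent or uniform angles) yields 0; a mean cosine
#' at or beyond the value attainable at `kappa_max` is clamped to
#' `kappa_max`, since the MLE diverges for perfectly straight tracks.
#'
#' @param theta turning angles in radians.
#' @param kappa_max upper clamp for the estimate (default 100, effectively
#'   deterministic motion).
#' @param tol root-finding tolerance on \eqn{\kappa}.
#' @return the estimated concentration, a single number in `[0, kappa_max]`.
#' @export
estimate_kappa <- function(theta, kappa_max = 100, tol = 1e-10) {
  if (!length(theta)) stop("cannot estimate kappa from zero turning angles")
  mc <- mean(cos(theta))
  if (mc <= 0) return(0)
  a1 <- function(k) besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
  if (a1(kappa_max) <= mc) return(kappa_max)
  stats::uniroot(function(k) a1(k) - mc, c(0, kappa_max), tol = tol)$root
}

#' Estimate the Rayleigh speed parameter
#'
#' Maximum-likelihood estimate for step widths \eqn{w} under the Rayleigh
#' model \eqn{p(w) = (w/\sigma^2)\exp(-w^2/2\sigma^2)}:
#' \eqn{\hat\sigma = \sqrt{\sum w^2 / (2n)}}.
#'
#' @param w step widths in micrometres (non-negative).
#' @return the estimated speed parameter \eqn{\hat\sigma}.
#' @export
estimate_sigma <- function(w) {
  if (!length(w)) stop("cannot estimate sigma from zero step widths")
  if (any(w < 0)) stop("step widths must be non-negative")
  s <- sqrt(sum(w^2) / (2 * length(w)))
  if (s <= 0) stop("degenerate cell: all step widths are zero")
  s
}

#' Half-width of the persistence cone
#'
#' Solves for the threshold angle \eqn{\theta_{thr}} such that a target-blind
#' cell's turning angle falls in \eqn{[-\theta_{thr}, +\theta_{thr}]} with
#' probability `p_ord` (the "ordinary move" probability).  The cone is an
#' illustration device: it plays no role in the p-value itself.
#'
#' @param kappa von Mises concentration.
#' @param p_ord probability mass the cone should contain (default 0.95).
#' @return half-width in radians, in `[0, pi]`.
#' @export
persistence_cone_halfwidth <- function(kappa, p_ord = 0.95) {
  stopifnot(kappa >= 0, p_ord > 0, p_ord < 1)
  if (kappa == 0) return(p_ord * pi)
  coeffs <- vm_fourier_coeffs(kappa)
  g <- function(d) vm_cummass(d, kappa, coeffs) - vm_cummass(-d, kappa, coeffs) - p_ord
  stats::uniroot(g, c(0, pi), tol = 1e-12)$root
}

#' Convert between significance level and band z-multiplier
#'
#' The per-bin confidence band of the reference histogram is
#' \eqn{[\mu_k - z\sigma_k, \mu_k + z\sigma_k]}.  Under a normal
#' approximation for the bin values, the one-sided probability of falling
#' above the upper (or below the lower) limit is \eqn{1 - \Phi(z)}.
#' `significance_to_z(0.05)` gives the default multiplier 1.645;
#' `z_to_significance(2.325)` recovers a level of about 0.01.
#'
#' @param alpha one-sided significance level in (0, 1).
#' @param z band half-width in reference standard deviations.
#' @return the corresponding multiplier or level.
#' @export
significance_to_z <- function(alpha) {
  stopifnot(alpha > 0, alpha < 1)
  stats::qnorm(1 - alpha)
}

#' @rdname significance_to_z
#' @export
z_to_significance <- function(z) {
  stats::pnorm(z, lower.tail = FALSE)
}
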