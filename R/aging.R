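# Age-dependent degradation rates (hazards), residual lifetimes and residual
# protein synthesis capacity.

# 4th/3rd-order numerical derivatives; one-sided near the left boundary so the
# function is never evaluated at negative times.
num_deriv1 <- function(f, x, h) {
  if (x >= 2 * h) {
    (8 * (f(x + h) - f(x - h)) - (f(x + 2 * h) - f(x - 2 * h))) / (12 * h)
  } else {
    v <- f(x + h * (0:4))
    (-25 * v[1] + 48 * v[2] - 36 * v[3] + 16 * v[4] - 3 * v[5]) / (12 * h)
  }
}
num_deriv2 <- function(f, x, h) {
  if (x >= 2 * h) {
    (-f(x + 2 * h) + 16 * f(x + h) - 30 * f(x) + 16 * f(x - h) -
       f(x - 2 * h)) / (12 * h^2)
  } else {
    v <- f(x + h * (0:4))
    (35 * v[1] - 104 * v[2] + 114 * v[3] - 56 * v[4] + 11 * v[5]) / (12 * h^2)
  }
}

deriv_step <- function(p) 0.02 / p$source$rate_scale

#' Age-dependent degradation rate (hazard) of a lifetime distribution
#'
#' The instantaneous degradation propensity of a molecule of age `a`:
#' \eqn{\omega(a) = f(a) / S(a)}. It is constant if and only if the lifetime
#' is exponential; a decreasing hazard means molecules stabilize as they age
#' (fast-slow decay), an increasing hazard means maturation steps precede
#' degradation (slow-fast decay).
#'
#' @param lt a [lifetime_distribution()].
#' @param a age(s) in minutes.
#' @return hazard rate(s) (1/min); `NA` with a warning where the survival
#'   has numerically vanished (the hazard is then unavailable, not zero).
#' @export
hazard_rate <- function(lt, a) {
  stopifnot(inherits(lt, "lifetime_distribution"))
  s <- lt$survival(a)
  bad <- !is.na(s) & s < 1e-300
  if (any(bad)) {
    warning("hazard unavailable beyond numerical support (survival underflow)")
    s[bad] <- NA_real_
  }
  lt$pdf(a) / s
}

#' Hazard deduced from a steady-state decay pattern
#'
#' Recovers the age-dependent degradation rate directly from the observable
#' pattern, without reference to the underlying lifetime model:
#' \deqn{\omega(a) = \frac{N_{rel}''(a)}{-N_{rel}'(a)},}
#' since \eqn{N_{rel}' = -S/\langle U\rangle} and
#' \eqn{N_{rel}'' = f/\langle U\rangle}. Derivatives are taken numerically
#' from `p$value` alone, so the function is a genuinely independent route to
#' the hazard and must agree with [hazard_rate()] of the source lifetime.
#'
#' @param p a steady-state `"decay_pattern"`.
#' @return vectorized function of age (min) returning rates (1/min).
#' @export
hazard_from_pattern <- function(p) {
  stopifnot(inherits(p, "decay_pattern"))
  if (p$mode != "steady_state")
    stop("pattern must be in steady_state mode (use hazard_from_pulse)")
  h <- deriv_step(p)
  function(a) {
    vapply(a, function(ai)
      num_deriv2(p$value, ai, h) / (-num_deriv1(p$value, ai, h)),
      numeric(1))
  }
}

#' Hazard deduced from a pulse decay pattern
#'
#' For a pulse experiment the pattern is the survival function itself, so the
#' hazard is its negative logarithmic derivative:
#' \eqn{\omega(t) = -\,d\log N_{rel}(t)/dt}. Both experimental designs give
#' the same age-dependent degradation rate.
#'
#' @param p a pulse-mode `"decay_pattern"`.
#' @return vectorized function of time (min) returning rates (1/min).
#' @export
hazard_from_pulse <- function(p) {
  stopifnot(inherits(p, "decay_pattern"))
  if (p$mode != "pulse")
    stop("pattern must be in pulse mode (use hazard_from_pattern)")
  h <- deriv_step(p)
  function(t) {
    vapply(t, function(ti) -num_deriv1(function(u) log(p$value(u)), ti, h),
           numeric(1))
  }
}

#' Residual lifetime density after transcription stop
#'
#' Density of the remaining time \eqn{R} to degradation of a molecule that
#' is still alive \eqn{\Delta t} minutes after transcription stopped in a
#' steady-state population:
#' \deqn{\phi(r;\Delta t) = \frac{S(\Delta t + r)}
#'       {\int_{\Delta t}^{\infty} S(u)\,du}.}
#' At \eqn{\Delta t = 0} this is the stationary residual-lifetime law
#' \eqn{S(r)/\langle U\rangle}.
#'
#' @param lt a [lifetime_distribution()].
#' @param dt delay since transcription stop (min).
#' @return vectorized density function of `r` (min).
#' @export
residual_density <- function(lt, dt) {
  stopifnot(inherits(lt, "lifetime_distribution"), dt >= 0)
  G <- lt$tail_integral(dt)
  if (!is.finite(G) || G <= 0) stop("delay beyond the support of the lifetime")
  function(r) lt$survival(dt + r) / G
}

#' Residual lifetime density after a pulse
#'
#' For a pulse cohort every molecule has age `t`, so the residual lifetime is
#' the conditional remaining lifetime: \eqn{\phi(r; t) = f(t + r)/S(t)}.
#'
#' @param lt a [lifetime_distribution()].
#' @param t common age of the cohort (min).
#' @return vectorized density function of `r` (min).
#' @export
residual_density_pulse <- function(lt, t) {
  stopifnot(inherits(lt, "lifetime_distribution"), t >= 0)
  s <- lt$survival(t)
  if (!is.finite(s) || s <= 0) stop("age beyond the support of the lifetime")
  function(r) lt$pdf(t + r) / s
}

#' Mean residual lifetime
#'
#' \eqn{\langle R\rangle(\Delta t) = \int_0^\infty r\,\phi(r;\Delta t)\,dr},
#' computed as \eqn{\int_0^\infty G(\Delta t + r)\,dr / G(\Delta t)} with
#' \eqn{G(t) = \int_t^\infty S}. Constant in \eqn{\Delta t} exactly for
#' exponential lifetimes; it grows with \eqn{\Delta t} when old molecules are
#' the stable ones (fast-slow) and shrinks when aging destabilizes
#' (slow-fast).
#'
#' @inheritParams residual_density
#' @return mean residual lifetime (min).
#' @export
mean_residual <- function(lt, dt = 0) {
  stopifnot(inherits(lt, "lifetime_distribution"), dt >= 0)
  G <- lt$tail_integral(dt)
  if (!is.finite(G) || G <= 0) stop("delay beyond the support of the lifetime")
  stats::integrate(function(r) lt$tail_integral(dt + r), 0, Inf,
                   rel.tol = 1e-9)$value / G
}

#' Residual protein synthesis capacity
#'
#' First-order proxy for the protein yield still obtainable from the
#' surviving mRNA population at delay \eqn{\Delta t}:
#' \eqn{C(\Delta t) \propto N_{rel}(\Delta t)\,\langle R\rangle(\Delta t)},
#' normalized so that \eqn{C(0) = 1}. Decays exactly exponentially iff the
#' lifetime is exponential (then \eqn{\langle R\rangle} is constant and
#' \eqn{C = N_{rel}}).
#'
#' @inheritParams residual_density
#' @return dimensionless capacity value(s); vectorized over `dt`.
#' @export
synthesis_capacity <- function(lt, dt) {
  stopifnot(inherits(lt, "lifetime_distribution"), all(dt >= 0))
  p <- steady_state_pattern(lt)
  r0 <- mean_residual(lt, 0)
  vapply(dt, function(d) p$value(d) * mean_residual(lt, d) / r0, numeric(1))
}

#' Stationary age density of surviving molecules
#'
#' At steady-state expression the ages of the molecules present in the cell
#' follow \eqn{g(a) = S(a)/\langle U\rangle} (the classical
#' inspection-paradox age law). Its mean is
#' \eqn{\langle U^2\rangle / (2\langle U\rangle)}.
#'
#' @param lt a [lifetime_distribution()].
#' @return vectorized density function of age (min).
#' @export
stationary_age_density <- function(lt) {
  stopifnot(inherits(lt, "lifetime_distribution"))
  function(a) lt$survival(a) / lt$mean
}
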