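#' Expression model: Poisson transcription + random lifetimes
#'
#' Couples a constant transcription rate \eqn{\nu} (Poisson arrivals of new
#' molecules per cell) to a lifetime distribution. Under balanced growth this
#' is an M/G/infinity system: the copy number is Poisson with mean
#' \eqn{\bar m = \nu\langle U\rangle} for *any* lifetime distribution, and it
#' remains Poisson at every delay after transcription stops.
#'
#' @param nu transcription rate (1/min), `> 0`.
#' @param lt a [lifetime_distribution()] with finite mean.
#' @return object of class `"expression_model"`.
#' @export
expression_model <- function(nu, lt) {
  stopifnot(inherits(lt, "lifetime_distribution"))
  if (!is.finite(nu) || nu <= 0) stop("`nu` must be > 0")
  if (!is.finite(nu * lt$mean)) stop("steady-state mean must be finite")
  structure(list(nu = nu, lt = lt), class = "expression_model")
}

#' @export
print.expression_model <- function(x, ...) {
  cat("Expression model: nu =", x$nu, "/min, <U> =",
      format(x$lt$mean, digits = 6), "min, steady-state mean =",
      format(x$nu * x$lt$mean, digits = 6), "molecules\n")
  invisible(x)
}

#' Stationary copy-number distribution
#'
#' Probability of `k` molecules per cell at steady state: Poisson with mean
#' \eqn{\nu\langle U\rangle}, irrespective of the shape of the lifetime
#' distribution.
#'
#' @param em an [expression_model()].
#' @param k non-negative integer count(s).
#' @return probability mass value(s).
#' @export
stationary_pmf <- function(em, k) {
  stopifnot(inherits(em, "expression_model"))
  if (any(k < 0)) stop("`k` must be non-negative")
  stats::dpois(k, em$nu * em$lt$mean)
}

#' Mean copy number after transcription stop
#'
#' \eqn{\mu(\Delta t) = \nu \int_{\Delta t}^{\infty} S(u)\,du}; at
#' \eqn{\Delta t = 0} this is the steady-state mean \eqn{\nu\langle U\rangle},
#' and \eqn{\mu(\Delta t)/\mu(0)} is exactly the steady-state decay pattern
#' \eqn{N_{rel}(\Delta t)}.
#'
#' @param em an [expression_model()].
#' @param dt delay(s) after the stop (min).
#' @return mean count(s).
#' @export
mean_after_stop <- function(em, dt) {
  stopifnot(inherits(em, "expression_model"), all(dt >= 0))
  em$nu * em$lt$tail_integral(dt)
}

#' Copy-number distribution after transcription stop
#'
#' The count at delay \eqn{\Delta t} is Poisson with mean
#' \eqn{\mu(\Delta t)} from [mean_after_stop()] — thinning a Poisson
#' population by independent survival keeps it Poisson.
#'
#' @inheritParams mean_after_stop
#' @param k non-negative integer count(s).
#' @return probability mass value(s).
#' @export
pmf_after_stop <- function(em, dt, k) {
  stopifnot(length(dt) == 1L)
  if (any(k < 0)) stop("`k` must be non-negative")
  stats::dpois(k, mean_after_stop(em, dt))
}

#' Survival probability of a molecule born uniformly in a window
#'
#' For a molecule whose birth time is uniform on \eqn{[0, T]} (the
#' conditional law of Poisson arrival times), the probability of still being
#' alive at \eqn{T + \Delta t} is
#' \deqn{p = \frac{1}{T}\int_0^T S(s + \Delta t)\, ds
#'         = \frac{G(\Delta t) - G(\Delta t + T)}{T}}
#' with \eqn{G(t) = \int_t^\infty S}. As \eqn{T \to \infty},
#' \eqn{\nu T p \to \mu(\Delta t)}: the finite-window binomial construction
#' converges to the Poisson law after the stop.
#'
#' @param lt a [lifetime_distribution()].
#' @param T window length (min), `> 0`.
#' @param dt extra delay beyond the window end (min).
#' @return a probability.
#' @export
survival_probability_window <- function(lt, T, dt = 0) {
  stopifnot(inherits(lt, "lifetime_distribution"), T > 0, dt >= 0)
  (lt$tail_integral(dt) - lt$tail_integral(dt + T)) / T
}

# Finite-window copy-number pmf (test harness only): number of survivors at
# T + dt out of a Poisson(nu*T) number of uniformly-born molecules, i.e. a
# Poisson mixture of binomials, summed explicitly. Converges to
# pmf_after_stop as T grows; kept internal because the limit law is the API.
pmf_finite_window <- function(em, T, dt, k) {
  p <- survival_probability_window(em$lt, T, dt)
  lambda <- em$nu * T
  nmax <- stats::qpois(1 - 1e-13, lambda)
  n <- 0:nmax
  wn <- stats::dpois(n, lambda)
  vapply(k, function(kk) sum(wn * stats::dbinom(kk, n, p)), numeric(1))
}
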