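#' Lifetime distribution of a single mRNA molecule
#'
#' Container for the distribution of the random lifetime \eqn{U}: density
#' \eqn{f(t)}, cumulative probability \eqn{F(t)}, survival
#' \eqn{S(t) = 1 - F(t)} and mean \eqn{\langle U\rangle}. All times are in
#' minutes, rates in 1/min.
#'
#' `tail_integral(t)` returns \eqn{\int_t^\infty S(u)\,du}, the quantity that
#' drives the steady-state decay pattern; when no analytic form is supplied it
#' falls back to adaptive quadrature on the survival function.
#'
#' @param pdf,cdf,survival vectorized functions of time (min).
#' @param mean mean lifetime \eqn{\langle U\rangle} (min).
#' @param provenance character tag recording which model produced the object.
#' @param chain optional generating [decay_chain()].
#' @param tail_integral optional vectorized analytic tail integral of the
#'   survival function.
#' @param rate_scale optional largest rate in the model (used to choose
#'   numerical differentiation steps downstream).
#' @param params optional named list of model parameters.
#' @return object of class `"lifetime_distribution"`.
#' @export
lifetime_distribution <- function(pdf, cdf, survival, mean,
                                  provenance = "custom", chain = NULL,
                                  tail_integral = NULL, rate_scale = NULL,
                                  params = NULL) {
  stopifnot(is.function(pdf), is.function(cdf), is.function(survival))
  if (!is.finite(mean) || mean <= 0)
    stop("`mean` must be a finite positive time")
  if (is.null(tail_integral)) {
    tail_integral <- function(t) {
      vapply(t, function(ti) {
        stats::integrate(survival, ti, Inf, rel.tol = 1e-10,
                         abs.tol = 1e-12)$value
      }, numeric(1))
    }
  }
  if (is.null(rate_scale)) rate_scale <- 1 / mean
  structure(list(pdf = pdf, cdf = cdf, survival = survival, mean = mean,
                 provenance = provenance, chain = chain,
                 tail_integral = tail_integral, rate_scale = rate_scale,
                 params = params),
            class = "lifetime_distribution")
}

#' @export
print.lifetime_distribution <- function(x, ...) {
  cat("mRNA lifetime distribution [", x$provenance, "]\n", sep = "")
  cat("  mean lifetime <U> =", format(x$mean, digits = 6), "min\n")
  if (!is.null(x$params))
    cat("  parameters:",
        paste(names(x$params), format(unlist(x$params), digits = 4),
              sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
mean.lifetime_distribution <- function(x, ...) x$mean

#' Phase-type lifetime distribution of a decay chain
#'
#' Computes the absorption-time (lifetime) distribution of a linear decay
#' chain from its matrix representation: with sub-generator \eqn{T} and exit
#' vector \eqn{t_0 = \delta},
#' \deqn{f(t) = \alpha e^{Tt} t_0, \quad S(t) = \alpha e^{Tt} \mathbf{1},
#'       \quad \langle U\rangle = -\alpha T^{-1}\mathbf{1}.}
#' The matrix exponential (scaling-and-squaring via [Matrix::expm()]) makes no
#' assumption on the rates, so this route is the brute-force oracle against
#' which the closed-form models can be checked.
#'
#' @param chain a [decay_chain()].
#' @return a [lifetime_distribution()].
#' @examples
#' lt <- lifetime_from_chain(decay_chain(2, 0.1, c(0.2, 0.02)))
#' lt$mean   # 20 min
#' @export
lifetime_from_chain <- function(chain) {
  stopifnot(inherits(chain, "decay_chain"))
  Tm <- chain_subgenerator(chain)
  alpha <- chain$initial_state
  t0 <- chain$delta
  ones <- rep(1, chain$n)
  Tinv1 <- solve(Tm, ones)
  expmv <- function(t) {
    # alpha * expm(T t) for one t
    as.numeric(alpha %*% as.matrix(Matrix::expm(Matrix::Matrix(Tm * t))))
  }
  evalv <- function(t, v) {
    vapply(t, function(ti) {
      if (ti < 0) return(NA_real_)
      sum(expmv(ti) * v)
    }, numeric(1))
  }
  lifetime_distribution(
    pdf = function(t) evalv(t, t0),
    cdf = function(t) 1 - evalv(t, ones),
    survival = function(t) evalv(t, ones),
    mean = -drop(alpha %*% Tinv1),
    provenance = "phase_type_chain",
    chain = chain,
    tail_integral = function(t) -evalv(t, Tinv1),
    rate_scale = max(c(chain$omega, chain$delta, 1e-12)),
    params = list(n = chain$n)
  )
}

#' Exponential lifetime (single rate-limiting step)
#'
#' When every state of the decay chain carries the same degradation rate
#' \eqn{\delta_i = \delta}, the lifetime density collapses to
#' \eqn{f(t) = \delta e^{-\delta t}} regardless of the chain length \eqn{n}
#' and of the transition rates \eqn{\omega_i}: maturation steps are invisible
#' to degradation. This is the one-parameter model of the fitting pipeline.
#'
#' @param delta degradation rate (1/min), `> 0`.
#' @return a [lifetime_distribution()].
#' @examples
#' lifetime_exponential(log(2) / 10)  # half-life 10 min
#' @export
lifetime_exponential <- function(delta) {
  if (!is.finite(delta) || delta <= 0) stop("`delta` must be > 0")
  lifetime_distribution(
    pdf = function(t) stats::dexp(t, delta),
    cdf = function(t) stats::pexp(t, delta),
    survival = function(t) exp(-delta * t),
    mean = 1 / delta,
    provenance = "exponential",
    chain = decay_chain(1, numeric(0), delta),
    tail_integral = function(t) exp(-delta * t) / delta,
    rate_scale = delta,
    params = list(delta = delta)
  )
}

#' First-step lifetime model (fast-slow decay)
#'
#' Closed form for the chain in which only the first degradation rate
#' differs: \eqn{\delta_1 = } `delta1`, \eqn{\delta_i = } `delta2` for
#' \eqn{i \ge 2}. After leaving state 1 all states look alike to
#' degradation, so the distribution is independent of the chain length
#' \eqn{n \ge 2} and of the transition rates beyond the first. With
#' \eqn{a = \omega + \delta_1}:
#' \deqn{f(t) = \delta_1 e^{-at}
#'   + \omega\delta_2 \frac{e^{-\delta_2 t} - e^{-a t}}{a - \delta_2},}
#' evaluated through an entire-function kernel so the degenerate point
#' \eqn{a = \delta_2} is handled by analytic continuation, not by a special
#' case failure. With `delta1 > delta2` the hazard decreases with age: such
#' molecules decay fast when young and stabilize (category "fast-slow").
#'
#' @param omega forward transition rate out of state 1 (1/min).
#' @param delta1 degradation rate in state 1 (1/min).
#' @param delta2 degradation rate in every later state (1/min); must be
#'   `> 0` whenever `omega > 0` (otherwise absorption would not be certain).
#' @return a [lifetime_distribution()].
#' @examples
#' lt <- lifetime_first_step(0.1, 0.2, 0.02)
#' lt$pdf(0)   # = delta1
#' lt$mean     # 20 min
#' @export
lifetime_first_step <- function(omega, delta1, delta2) {
  rates <- c(omega = omega, delta1 = delta1, delta2 = delta2)
  if (anyNA(rates) || any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and non-negative")
  if (omega > 0 && delta2 <= 0)
    stop("absorption impossible: omega > 0 requires delta2 > 0")
  if (omega == 0 && delta1 <= 0)
    stop("all effective rates are zero")
  a <- omega + delta1
  w <- if (omega > 0) omega / a else 0
  occ <- function(t) {
    if (omega > 0) erlang_exp_occupancy(t, 1, a, delta2) else numeric(length(t))
  }
  surv <- function(t) exp(-a * t) + w * occ(t)
  m <- (1 + if (omega > 0) omega / delta2 else 0) / a
  lifetime_distribution(
    pdf = function(t) delta1 * exp(-a * t) + if (omega > 0) delta2 * w * occ(t) else 0,
    cdf = function(t) 1 - surv(t),
    survival = surv,
    mean = m,
    provenance = "first_step",
    chain = decay_chain(2, omega, c(delta1, delta2)),
    tail_integral = function(t) {
      exp(-a * t) / a +
        (if (omega > 0) (omega / (a * delta2)) * (occ(t) + exp(-a * t)) else 0)
    },
    rate_scale = max(rates),
    params = as.list(rates)
  )
}

#' Last-step lifetime model (slow-fast decay)
#'
#' Closed form for the chain in which degradation acts mainly from the final
#' state: \eqn{\delta_i = } `delta_pre` for \eqn{i < n} and
#' \eqn{\delta_n = } `delta_last`, all forward rates equal to `omega`. With
#' `delta_pre = 0` (the default of the fitting pipeline) the lifetime is the
#' convolution of an Erlang(`n - 1`, `omega`) maturation time with an
#' exponential(`delta_last`) degradation time: young molecules are protected
#' until the chain of slow modifications completes, so the hazard rises from
#' 0 toward `delta_last` (category "slow-fast").
#'
#' @param omega common forward transition rate (1/min).
#' @param delta_pre degradation rate of the pre-terminal states (1/min),
#'   default 0.
#' @param delta_last degradation rate of state `n` (1/min).
#' @param n chain length, `>= 2`; default 5, reflecting the roughly five
#'   biochemical stages of deadenylation-dependent mRNA decay.
#' @return a [lifetime_distribution()].
#' @examples
#' lt <- lifetime_last_step(0.5, 0, 0.1, n = 5)
#' lt$mean     # 4/0.5 + 1/0.1 = 18 min
#' lt$pdf(0)   # 0: absorption requires reaching state n
#' @export
lifetime_last_step <- function(omega, delta_pre = 0, delta_last, n = 5) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L) stop("`n` must be an integer >= 2")
  rates <- c(omega = omega, delta_pre = delta_pre, delta_last = delta_last)
  if (anyNA(rates) || any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and non-negative")
  if (omega > 0 && delta_last <= 0)
    stop("absorption impossible: omega > 0 requires delta_last > 0")
  if (omega == 0 && delta_pre <= 0)
    stop("all effective rates are zero")
  m <- n - 1L
  a <- omega + delta_pre
  w <- omega / a                       # per-step forward probability
  sum_pre <- function(t) exp(-delta_pre * t) * stats::ppois(m - 1, omega * t)
  last <- function(t) {
    if (omega > 0) w^m * erlang_exp_occupancy(t, m, a, delta_last)
    else numeric(length(t))
  }
  surv <- function(t) sum_pre(t) + last(t)
  mean_lt <- sum(w^(0:(m - 1))) / a + if (omega > 0) w^m / delta_last else 0
  lifetime_distribution(
    pdf = function(t) delta_pre * sum_pre(t) +
      if (omega > 0) delta_last * last(t) else 0,
    cdf = function(t) 1 - surv(t),
    survival = surv,
    mean = mean_lt,
    provenance = "last_step",
    chain = decay_chain(n, rep(omega, m), c(rep(delta_pre, m), delta_last)),
    tail_integral = function(t) {
      k <- seq_len(m)
      pre <- rowSums(outer(a * t, k, function(z, kk)
        stats::pgamma(z, shape = kk, lower.tail = FALSE)) *
          matrix(w^(k - 1) / a, length(t), m, byrow = TRUE))
      pre + if (omega > 0)
        (last(t) + w^m * stats::pgamma(a * t, shape = m, lower.tail = FALSE)) /
          delta_last else 0
    },
    rate_scale = max(rates),
    params = c(as.list(rates), list(n = n))
  )
}
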