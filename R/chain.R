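#' Linear absorbing decay chain
#'
#' Represents mRNA maturation/degradation as a linear continuous-time Markov
#' chain with transient states \eqn{1..n}. A molecule in state \eqn{i} either
#' undergoes the next biochemical modification (transition \eqn{i \to i+1} at
#' rate \eqn{\omega_i}) or is degraded (transition to the absorbing state 0 at
#' rate \eqn{\delta_i}). The absorption time is the single-molecule lifetime
#' \eqn{U}; its distribution is phase-type (see [lifetime_from_chain()]).
#'
#' @param n integer chain length (number of transient states, \eqn{\ge 1}).
#' @param omega numeric vector of `n - 1` forward transition rates (1/min).
#' @param delta numeric vector of `n` degradation rates (1/min).
#' @param initial_state probability vector over states `1..n`; default puts
#'   all mass on state 1 (a newly transcribed molecule).
#'
#' @return An object of class `"decay_chain"` with fields `n`, `omega`,
#'   `delta`, `initial_state`.
#'
#' @details Absorption must be certain: a molecule walking forward from any
#'   state with positive initial mass must meet a strictly positive
#'   degradation rate at the first state it cannot leave forward (the chain
#'   is linear, so this reduces to checking the first index `j >= s` with
#'   `omega[j] == 0`, taking `omega[n] = 0`).
#'
#' @examples
#' decay_chain(1, numeric(0), 0.1)                  # single rate-limiting step
#' decay_chain(5, rep(0.5, 4), c(0, 0, 0, 0, 0.1))  # degradation from state n
#' @export
decay_chain <- function(n, omega = numeric(0), delta, initial_state = NULL) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("`n` must be a single integer >= 1")
  omega <- as.numeric(omega)
  delta <- as.numeric(delta)
  if (length(omega) != n - 1L)
    stop("`omega` must have length n - 1 (got ", length(omega), ")")
  if (length(delta) != n)
    stop("`delta` must have length n (got ", length(delta), ")")
  if (anyNA(omega) || anyNA(delta) || any(omega < 0) || any(delta < 0))
    stop("all rates must be finite and non-negative")
  if (is.null(initial_state)) {
    initial_state <- c(1, rep(0, n - 1L))
  } else {
    initial_state <- as.numeric(initial_state)
    if (length(initial_state) != n || anyNA(initial_state) ||
        any(initial_state < 0) || abs(sum(initial_state) - 1) > 1e-12)
      stop("`initial_state` must be a probability vector of length n")
  }
  # certain absorption: for every start with positive mass, the first
  # forward-blocked state must have delta > 0
  omega_ext <- c(omega, 0)
  for (s in which(initial_state > 0)) {
    blocked <- which(omega_ext[s:n] == 0)[1] + s - 1L
    if (delta[blocked] == 0)
      stop("absorption impossible: no exit rate on the path from state ", s,
           " (state ", blocked, " has omega = 0 and delta = 0)")
  }
  structure(list(n = n, omega = omega, delta = delta,
                 initial_state = initial_state),
            class = "decay_chain")
}

#' @export
print.decay_chain <- function(x, ...) {
  cat("Linear absorbing decay chain with", x$n, "transient state(s)\n")
  if (x$n > 1) cat("  omega (i -> i+1):", format(x$omega, digits = 4), "\n")
  cat("  delta (i -> 0):  ", format(x$delta, digits = 4), "\n")
  if (any(x$initial_state[-1] > 0))
    cat("  initial state:   ", format(x$initial_state, digits = 4), "\n")
  invisible(x)
}

# Sub-generator T (n x n, bidiagonal) of the transient block; exit vector is
# delta.  T[i,i] = -(omega_i + delta_i), T[i,i+1] = omega_i, omega_n = 0.
chain_subgenerator <- function(chain) {
  n <- chain$n
  Tm <- diag(-(c(chain$omega, 0) + chain$delta), n, n)
  if (n > 1) Tm[cbind(seq_len(n - 1), seq(2, n))] <- chain$omega
  Tm
}

# Raw moments of the absorption time: E[U^k] = (-1)^k k! alpha T^{-k} 1.
chain_moment <- function(chain, k = 1) {
  Tm <- chain_subgenerator(chain)
  v <- rep(1, chain$n)
  for (i in seq_len(k)) v <- solve(Tm, v)
  (-1)^k * factorial(k) * drop(chain$initial_state %*% v)
}
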