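# Shared fixtures: the canonical assay grid, a model zoo, and small utilities.

grid_s1 <- c(0, 5, 10, 15, 20, 30, 40, 50, 60)

# reference models used throughout: one per closed form, plus a general-rate
# chain only reachable through the matrix-exponential route
model_zoo <- function() {
  list(
    exponential = lifetime_exponential(0.1),
    first_step  = lifetime_first_step(0.1, 0.2, 0.02),
    last_step   = lifetime_last_step(0.5, 0, 0.1, n = 5),
    last_step_pre = lifetime_last_step(0.3, 0.01, 0.25, n = 4),
    chain = lifetime_from_chain(
      decay_chain(3, c(0.4, 0.15), c(0.05, 0.01, 0.3)))
  )
}

# log-spaced time grid covering [0, span * mean], as used for the
# oracle-equivalence checks
log_grid <- function(mean, span = 10, k = 40) {
  c(0, exp(seq(log(mean / 100), log(span * mean), length.out = k)))
}

# random valid linear chain (uses the current RNG state)
random_chain <- function(nmax = 8) {
  n <- sample(2:nmax, 1)
  omega <- stats::runif(n - 1, 0.05, 1)
  delta <- stats::runif(n, 0, 0.3) * stats::rbinom(n, 1, 0.6)
  delta[n] <- stats::runif(1, 0.02, 0.3)   # certain absorption
  decay_chain(n, omega, delta)
}

# decay table straight from an analytic pattern (suppresses the level(0)=1
# renormalization warning that exact patterns trigger by construction)
table_from_pattern <- function(id, p, times = grid_s1) {
  suppressWarnings(decay_table(id, times, p$value(times)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) /
                  pmax(abs(expected), .Machine$double.eps)), tol)
}
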