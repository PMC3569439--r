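# Numerical kernel shared by all closed-form lifetime models.
#
# psi_m(x) = sum_{i >= 0} x^i / (i + m)!  =  x^{-m} (e^x - sum_{j < m} x^j / j!)
#
# This is the function through which every exponential-difference term of the
# closed forms is expressed, so the degenerate "equal rates" points (x -> 0)
# are interior points of an entire function instead of 0/0 limits.

# Vectorized over x; m is a single non-negative integer.
# Three regimes (boundary B = max(12, m + 3); at |x| = 12 the series'
# largest term is ~1e3 times the result, so cancellation stays ~1e-12):
#   |x| <= B : direct series (terms damped by (i+m)! for larger m)
#   x  >  B : regularized incomplete gamma, Sum_{j>=m} x^j/j! = e^x P(Pois(x)>=m)
#   x  < -B : forward recurrence psi_k = (psi_{k-1} - 1/(k-1)!)/x from psi_0=e^x,
#             stable because |x| > m there (errors are divided by x each step)
psi_mk <- function(x, m) {
  stopifnot(length(m) == 1L, m >= 0, m == round(m))
  out <- numeric(length(x))
  B <- max(12, m + 3)
  small <- abs(x) <= B
  big <- x > B
  neg <- x < -B

  if (any(small)) {
    xs <- x[small]
    term <- rep(1 / factorial(m), length(xs))
    acc <- term
    i <- 0
    repeat {
      term <- term * xs / (i + m + 1)
      acc <- acc + term
      i <- i + 1
      if (all(abs(term) <= 1e-18 * abs(acc)) || i > 200) break
    }
    out[small] <- acc
  }
  if (any(big)) {
    xb <- x[big]
    if (m == 0) {
      out[big] <- exp(xb)
    } else {
      # exp(x) * pgamma(x, m) / x^m, assembled in log space to dodge overflow
      out[big] <- exp(xb + stats::pgamma(xb, shape = m, log.p = TRUE) -
                        m * log(xb))
    }
  }
  if (any(neg)) {
    xn <- x[neg]
    acc <- exp(xn)           # psi_0
    if (m >= 1) {
      for (k in seq_len(m)) acc <- (acc - 1 / factorial(k - 1)) / xn
    }
    out[neg] <- acc
  }
  out
}

# Occupancy of the terminal stage of an Erlang(m, a) -> Exp(d) pipeline at
# time t (probability that the m holding stages at rate a are complete and the
# final Exp(d) stage has not fired):
#   L(t) = a^m t^m e^{-a t} psi_m((a - d) t)
# The absorption density of that pipeline is d * L(t).  Vectorized over t.
erlang_exp_occupancy <- function(t, m, a, d) {
  stopifnot(m >= 1, a > 0)
  x <- (a - d) * t
  out <- numeric(length(t))
  pos <- t > 0
  if (!any(pos)) return(out)
  tp <- t[pos]
  xp <- x[pos]
  res <- numeric(length(tp))
  big <- xp > max(12, m + 3)
  if (any(big)) {
    # a^m t^m e^{-at} psi_m(x) = (a/(a-d))^m e^{-dt} pgamma(x, m); cancellation-free
    res[big] <- exp(m * (log(a) - log(a - d)) - d * tp[big] +
                      stats::pgamma(xp[big], shape = m, log.p = TRUE))
  }
  if (any(!big)) {
    res[!big] <- exp(m * log(a * tp[!big]) - a * tp[!big]) *
      psi_mk(xp[!big], m)
  }
  out[pos] <- res
  out
}
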