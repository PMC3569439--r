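# Closed-form lifetime models versus the matrix-exponential phase-type route
# (two fully independent code paths), plus frozen values from a 40-digit
# symbolic oracle.

test_that("frozen symbolic-oracle values: first-step closed form", {
  lt <- lifetime_first_step(0.1, 0.2, 0.02)
  expect_rel_equal(lt$pdf(7.5), 0.026474907425681392145542, 1e-12)
  expect_rel_equal(lt$survival(7.5), 0.375152350227290576228152, 1e-12)
  expect_rel_equal(lt$tail_integral(7.5), 15.5956407745085987079111, 1e-12)
  expect_equal(lt$mean, 20, tolerance = 1e-12)
  expect_equal(lt$pdf(0), 0.2, tolerance = 1e-12)   # pdf(0) = delta1
  expect_equal(lt$cdf(0), 0)
})

test_that("frozen symbolic-oracle values: last-step closed form", {
  lt <- lifetime_last_step(0.5, 0, 0.1, n = 5)
  expect_rel_equal(lt$pdf(12), 0.051897916038092395093815, 1e-12)
  expect_rel_equal(lt$survival(12), 0.670183043157571814743907, 1e-12)
  expect_rel_equal(lt$tail_integral(12), 7.16783584078899353097156, 1e-12)
  expect_equal(lt$mean, 18, tolerance = 1e-12)      # 4/omega + 1/delta_last
  expect_equal(lt$pdf(0), 0)                        # must reach state n first
  # general pre-terminal degradation rate
  lt2 <- lifetime_last_step(0.3, 0.01, 0.25, n = 4)
  expect_rel_equal(lt2$pdf(6), 0.048374367765617456910056, 1e-12)
  expect_rel_equal(lt2$survival(6), 0.854047576239956008720425, 1e-12)
  expect_rel_equal(lt2$tail_integral(6), 7.30476897641310954914154, 1e-12)
  expect_rel_equal(lt2$mean, 12.9938572051962001946897, 1e-12)
  expect_equal(lt2$pdf(0), 0.01)                    # = delta_pre
})

test_that("every closed form equals the phase-type oracle pointwise", {
  pairs <- list(
    list(lifetime_exponential(0.1), decay_chain(1, numeric(0), 0.1)),
    list(lifetime_first_step(0.1, 0.2, 0.02),
         decay_chain(5, rep(0.1, 4), c(0.2, rep(0.02, 4)))),
    list(lifetime_last_step(0.5, 0, 0.1, n = 5),
         decay_chain(5, rep(0.5, 4), c(0, 0, 0, 0, 0.1))),
    list(lifetime_last_step(0.3, 0.01, 0.25, n = 4),
         decay_chain(4, rep(0.3, 3), c(0.01, 0.01, 0.01, 0.25)))
  )
  for (pr in pairs) {
    closed <- pr[[1]]; oracle <- lifetime_from_chain(pr[[2]])
    tt <- log_grid(closed$mean)
    expect_lt(max(abs(closed$pdf(tt) - oracle$pdf(tt))), 1e-8)
    expect_lt(max(abs(closed$survival(tt) - oracle$survival(tt))), 1e-8)
    expect_lt(max(abs(closed$tail_integral(tt) -
                        oracle$tail_integral(tt))), 1e-7)
  }
})

test_that("equal degradation rates give the exponential density independent of n and omega", {
  set.seed(11)
  delta <- 0.07
  for (n in 2:8) {
    ch <- decay_chain(n, stats::runif(n - 1, 0.01, 2), rep(delta, n))
    lt <- lifetime_from_chain(ch)
    tt <- log_grid(1 / delta, span = 8, k = 25)
    expect_lt(max(abs(lt$pdf(tt) - delta * exp(-delta * tt))), 1e-8)
  }
  # the 4-state example: pointwise equality with the exponential closed form
  lt4 <- lifetime_from_chain(decay_chain(4, rep(0.33, 3), rep(0.1, 4)))
  tt <- seq(0, 100, by = 2.5)
  expect_lt(max(abs(lt4$pdf(tt) - lifetime_exponential(0.1)$pdf(tt))), 1e-8)
})

test_that("first-step model is independent of chain length for n >= 2", {
  set.seed(12)
  for (rep in 1:5) {
    omega <- stats::runif(1, 0.02, 1)
    d1 <- stats::runif(1, 0.01, 0.5)
    d2 <- stats::runif(1, 0.005, 0.5)
    closed <- lifetime_first_step(omega, d1, d2)
    tt <- log_grid(closed$mean, span = 10, k = 20)
    for (n in c(2, 4, 7)) {
      ch <- decay_chain(n, rep(omega, n - 1), c(d1, rep(d2, n - 1)))
      expect_lt(max(abs(closed$pdf(tt) -
                          lifetime_from_chain(ch)$pdf(tt))), 1e-8)
    }
  }
})

test_that("degenerate rate coincidences are handled by analytic limits", {
  # omega + delta1 = delta2: the naive closed form is 0/0 here
  deg <- lifetime_first_step(0.05, 0.05, 0.1)
  oracle <- lifetime_from_chain(decay_chain(2, 0.05, c(0.05, 0.1)))
  tt <- seq(0, 120, by = 3)
  expect_lt(max(abs(deg$pdf(tt) - oracle$pdf(tt))), 1e-6)
  # neighborhood of the singular point
  for (eps in c(-1e-7, -1e-10, 1e-10, 1e-7)) {
    near <- lifetime_first_step(0.05, 0.05, 0.1 + eps)
    expect_lt(max(abs(near$pdf(tt) - deg$pdf(tt))), 1e-6)
  }
  # last-step with omega = delta_last (Erlang limit)
  deg2 <- lifetime_last_step(0.2, 0, 0.2, n = 5)
  tt2 <- seq(0, 100, by = 2.5)
  expect_lt(max(abs(deg2$pdf(tt2) -
                      stats::dgamma(tt2, shape = 5, rate = 0.2))), 1e-10)
  # first_step with delta1 = delta2 collapses to the exponential form
  same <- lifetime_first_step(0.7, 0.04, 0.04)
  expect_lt(max(abs(same$pdf(tt) - lifetime_exponential(0.04)$pdf(tt))),
            1e-12)
})

test_that("normalization and mean identities hold across the zoo", {
  for (lt in model_zoo()) {
    expect_equal(stats::integrate(lt$pdf, 0, Inf, rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-6)
    expect_equal(stats::integrate(lt$survival, 0, Inf,
                                  rel.tol = 1e-10)$value / lt$mean, 1,
                 tolerance = 1e-6)
    expect_equal(lt$cdf(50) + lt$survival(50), 1, tolerance = 1e-12)
    expect_equal(lt$cdf(0), 0)
  }
})

test_that("constructors reject impossible or absorbing-free models", {
  expect_error(lifetime_exponential(0), "> 0")
  expect_error(lifetime_first_step(0.5, 0.2, 0), "absorption")
  expect_error(lifetime_first_step(0, 0, 0.5), "zero")
  expect_error(lifetime_last_step(0.5, 0, 0.1, n = 1), ">= 2")
  expect_error(lifetime_last_step(0.5, 0.1, 0, n = 5), "absorption")
  # omega = 0 edge cases degrade gracefully to exponentials
  expect_equal(lifetime_first_step(0, 0.2, 0)$mean, 5, tolerance = 1e-12)
  expect_equal(lifetime_last_step(0, 0.1, 0, n = 3)$mean, 10,
               tolerance = 1e-12)
})
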