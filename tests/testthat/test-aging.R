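test_that("hazard of the reference models has the expected shape", {
  expect_equal(hazard_rate(lifetime_exponential(0.1), c(0, 7, 80)),
               rep(0.1, 3), tolerance = 1e-12)
  # first-step: starts at delta1, decreases toward delta2
  lt9 <- lifetime_first_step(0.1, 0.2, 0.02)
  expect_equal(hazard_rate(lt9, 0), 0.2, tolerance = 1e-12)
  h9 <- hazard_rate(lt9, c(0, 20, 100, 300))
  expect_true(all(diff(h9) < 0))
  expect_equal(h9[4], 0.02, tolerance = 1e-3)
  # last-step: starts at 0, increases toward delta_last
  lt10 <- lifetime_last_step(0.5, 0, 0.1, n = 5)
  expect_equal(hazard_rate(lt10, 0), 0)
  h10 <- hazard_rate(lt10, c(0, 10, 50, 300))
  expect_true(all(diff(h10) > 0))
  expect_equal(h10[4], 0.1, tolerance = 1e-3)
  # beyond numerical support the hazard is unavailable, not zero
  expect_warning(h <- hazard_rate(lifetime_exponential(1), 800),
                 "unavailable|underflow")
  expect_true(is.na(h))
})

test_that("the three hazard routes agree for every model in the zoo", {
  # definition f/S, steady-state pattern curvature ratio, pulse log-slope
  for (lt in model_zoo()) {
    hp <- hazard_from_pattern(steady_state_pattern(lt))
    hq <- hazard_from_pulse(pulse_pattern(lt))
    aa <- c(2, 8, 20, 45)
    ref <- hazard_rate(lt, aa)
    expect_rel_equal(hp(aa), ref, 1e-5)
    expect_rel_equal(hq(aa), ref, 1e-5)
  }
  expect_error(hazard_from_pattern(pulse_pattern(lifetime_exponential(1))),
               "steady_state")
  expect_error(hazard_from_pulse(
    steady_state_pattern(lifetime_exponential(1))), "pulse")
})

test_that("exp(-integrated hazard) reconstructs the survival function", {
  for (lt in model_zoo()[c("exponential", "first_step", "last_step")]) {
    for (a in c(5, 20, 60)) {
      cum <- stats::integrate(function(u) hazard_rate(lt, u), 0, a,
                              rel.tol = 1e-10)$value
      expect_equal(exp(-cum), lt$survival(a), tolerance = 1e-6)
    }
  }
})

test_that("residual lifetime densities normalize and obey the classical laws", {
  lt9 <- lifetime_first_step(0.1, 0.2, 0.02)
  lt10 <- lifetime_last_step(0.5, 0, 0.1, n = 5)
  for (lt in list(lt9, lt10)) {
    for (dt in c(0, 10, 60)) {
      phi <- residual_density(lt, dt)
      expect_equal(stats::integrate(phi, 0, Inf, rel.tol = 1e-9)$value, 1,
                   tolerance = 1e-6)
    }
  }
  # stationary residual law at dt = 0: survival/mean
  phi0 <- residual_density(lt9, 0)
  rr <- c(1, 5, 30)
  expect_equal(phi0(rr), lt9$survival(rr) / lt9$mean, tolerance = 1e-12)
  # memorylessness: exponential residuals are the lifetime itself at any dt
  lte <- lifetime_exponential(0.1)
  for (dt in c(0, 7, 33)) {
    expect_equal(residual_density(lte, dt)(rr), 0.1 * exp(-0.1 * rr),
                 tolerance = 1e-9)
  }
  # pulse residuals: f(t+r)/S(t); at t = 0 the density itself
  expect_equal(residual_density_pulse(lt10, 0)(rr), lt10$pdf(rr),
               tolerance = 1e-12)
  phi50 <- residual_density_pulse(lt10, 50)
  expect_equal(stats::integrate(phi50, 0, Inf, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
})

test_that("mean residual lifetime: moment identity and aging directions", {
  # at dt = 0 the stationary mean residual is <U^2>/(2<U>)
  for (lt in model_zoo()) {
    if (is.null(lt$chain)) next
    m2 <- chain_moment(lt$chain, 2)
    expect_rel_equal(mean_residual(lt, 0), m2 / (2 * lt$mean), 1e-6)
  }
  expect_equal(mean_residual(lifetime_exponential(0.1), 0), 10,
               tolerance = 1e-6)
  expect_equal(mean_residual(lifetime_exponential(0.1), 25), 10,
               tolerance = 1e-6)
  # fast-slow (delta1 > delta2): survivors stabilize, <R> increases
  lt9 <- lifetime_first_step(0.1, 0.2, 0.02)
  r9 <- vapply(c(0, 10, 30, 60), function(d) mean_residual(lt9, d),
               numeric(1))
  expect_true(all(diff(r9) > 0))
  # slow-fast (terminal degradation): survivors mature, <R> decreases
  lt10 <- lifetime_last_step(0.5, 0, 0.1, n = 5)
  r10 <- vapply(c(0, 10, 30, 60), function(d) mean_residual(lt10, d),
                numeric(1))
  expect_true(all(diff(r10) < 0))
})

test_that("synthesis capacity is exponential iff the lifetime is", {
  lte <- lifetime_exponential(0.05)
  dts <- c(0, 10, 25, 50)
  expect_equal(synthesis_capacity(lte, dts), exp(-0.05 * dts),
               tolerance = 1e-6)
  # non-exponential model: capacity deviates from the exponential through
  # its own half-life by more than 1e-3 somewhere
  lt10 <- lifetime_last_step(0.5, 0, 0.1, n = 5)
  hl <- pattern_half_life(steady_state_pattern(lt10))
  dev <- abs(synthesis_capacity(lt10, dts) - exp(-log(2) * dts / hl))
  expect_gt(max(dev), 1e-3)
  expect_equal(synthesis_capacity(lt10, 0), 1, tolerance = 1e-9)
})

test_that("stationary age density is survival/mean with the right mean age", {
  lte <- lifetime_exponential(0.1)
  g <- stationary_age_density(lte)
  aa <- c(0, 5, 20)
  expect_equal(g(aa), 0.1 * exp(-0.1 * aa), tolerance = 1e-12)
  lt10 <- lifetime_last_step(0.5, 0, 0.1, n = 5)
  g10 <- stationary_age_density(lt10)
  expect_equal(stats::integrate(g10, 0, Inf, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  mean_age <- stats::integrate(function(a) a * g10(a), 0, Inf,
                               rel.tol = 1e-9)$value
  expect_rel_equal(mean_age, chain_moment(lt10$chain, 2) / (2 * lt10$mean),
                   1e-6)
})

test_that("memorylessness characterizes the exponential across the zoo", {
  dts <- c(0, 10, 40)
  for (nm in names(model_zoo())) {
    lt <- model_zoo()[[nm]]
    r <- vapply(dts, function(d) mean_residual(lt, d), numeric(1))
    spread <- max(r) - min(r)
    if (nm == "exponential") expect_lt(spread, 1e-6)
    else expect_gt(spread, 1e-6)
  }
})
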