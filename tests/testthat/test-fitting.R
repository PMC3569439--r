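test_that("decay_table enforces the level and grid invariants", {
  expect_warning(tb <- decay_table("g", grid_s1,
                                   c(0.99, exp(-0.05 * grid_s1[-1]))),
                 "renormalizing")
  expect_equal(tb$levels[1], 1)
  expect_equal(tb$levels[2], exp(-0.25) / 0.99, tolerance = 1e-12)
  expect_error(decay_table("g", grid_s1, c(0.5, exp(-0.05 * grid_s1[-1]))),
               "away from 1")
  expect_error(decay_table("g", c(0, 5, 5, 10), c(1, 0.9, 0.8, 0.7)),
               "strictly increasing")
  expect_error(decay_table("g", c(5, 10, 15), c(1, 0.9, 0.8)), "t = 0")
  expect_error(decay_table("g", c(0, 5), c(1, 0.9, 0.8)), "equal length")
})

test_that("rss is the plain sum of squared residuals", {
  lt <- lifetime_exponential(0.05)
  p <- steady_state_pattern(lt)
  tb <- table_from_pattern("g", p)
  expect_equal(rss(tb, p), 0)
  shifted <- suppressWarnings(
    decay_table("g", grid_s1, p$value(grid_s1) + 0.1,
                renormalize_tol = 0.2))
  # renormalization divides by 1.1, so compare against the renormalized curve
  expect_equal(sum((shifted$levels - p$value(grid_s1))^2),
               rss(shifted, p), tolerance = 1e-12)
  # without renormalization interference: 9 residuals of 0.1 each
  fake <- list(value = function(t) p$value(t) - 0.1)
  tb2 <- table_from_pattern("g", p)
  expect_equal(rss(tb2, fake), 9 * 0.01, tolerance = 1e-12)
})

test_that("noiseless tables return their generating parameters", {
  cases <- list(
    list(variant = "exponential", lt = lifetime_exponential(0.05),
         truth = c(delta1 = 0.05)),
    list(variant = "first_step", lt = lifetime_first_step(0.1, 0.2, 0.02),
         truth = c(omega = 0.1, delta1 = 0.2, delta2 = 0.02)),
    list(variant = "last_step", lt = lifetime_last_step(0.5, 0, 0.1, n = 5),
         truth = c(omega = 0.5, delta2 = 0.1))
  )
  for (cs in cases) {
    tb <- table_from_pattern(cs$variant, steady_state_pattern(cs$lt))
    f <- fit_variant(tb, cs$variant)
    expect_lt(f$rss, 1e-10)
    for (nm in names(cs$truth)) {
      expect_rel_equal(f[[nm]], cs$truth[[nm]], 1e-4)
    }
    expect_rel_equal(f$mean_lifetime, cs$lt$mean, 1e-4)
  }
})

test_that("model selection applies the 10% rule and tie-breaks", {
  # noiseless truths classify into their own category
  tb_exp <- table_from_pattern(
    "e", steady_state_pattern(lifetime_exponential(0.05)))
  tb_fs <- table_from_pattern(
    "f", steady_state_pattern(lifetime_first_step(0.1, 0.2, 0.02)))
  tb_ls <- table_from_pattern(
    "l", steady_state_pattern(lifetime_last_step(0.5, 0, 0.1, n = 5)))
  s_exp <- select_and_classify(tb_exp)
  s_fs <- select_and_classify(tb_fs)
  s_ls <- select_and_classify(tb_ls)
  expect_equal(s_exp$category, 0L)   # RSS tie resolves to fewer parameters
  expect_equal(s_fs$category, 2L)
  expect_equal(s_ls$category, 1L)
  expect_gt(s_fs$improvement, 0.10)
  expect_gt(s_ls$improvement, 0.10)
  # the accepted fit records the exponential baseline
  expect_true(s_fs$rss <= 0.9 * s_fs$rss_exponential)
})

test_that("the exponential model is nested in both variants", {
  # first_step: delta1 = delta2 reproduces the exponential exactly;
  # last_step needs the free pre-terminal rate for exact nesting
  set.seed(31)
  for (r in 1:3) {
    delta <- stats::runif(1, 0.02, 0.08)
    v <- exp(-delta * grid_s1)
    lv <- v + c(0, stats::rnorm(8, 0, 0.03))
    tb <- suppressWarnings(decay_table("g", grid_s1, pmax(lv, 1e-3)))
    r_exp <- fit_variant(tb, "exponential")$rss
    expect_lte(fit_variant(tb, "first_step")$rss, r_exp + 1e-9)
    expect_lte(fit_variant(tb, "last_step", free_pre = TRUE)$rss,
               r_exp + 1e-9)
  }
})

test_that("exponential fits overestimate the half-life of contrasted fast-slow decay", {
  # molecules either die fast while young or persist: the single-rate fit
  # suggests a half-life about twice the true one
  lt <- lifetime_first_step(0.005, 0.3, 0.01)
  p <- steady_state_pattern(lt)
  true_hl <- pattern_half_life(p)
  f_exp <- fit_variant(table_from_pattern("mgs1_like", p), "exponential")
  expect_gt(f_exp$half_life, 1.5 * true_hl)
})

test_that("batch_fit aggregates results, failures and summaries", {
  tabs <- list(
    table_from_pattern("a", steady_state_pattern(lifetime_exponential(0.05))),
    table_from_pattern("b", steady_state_pattern(
      lifetime_first_step(0.1, 0.2, 0.02))),
    table_from_pattern("c", steady_state_pattern(
      lifetime_last_step(0.5, 0, 0.1, n = 5)))
  )
  bf <- batch_fit(tabs)
  expect_length(bf$failures, 0)
  expect_equal(sum(bf$summary$category_counts), 3)
  expect_equal(unname(bf$summary$category_counts), c(1, 1, 1))
  expect_equal(bf$summary$frac_rss_below, 1)   # all noiseless
})
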