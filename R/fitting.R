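#' Per-gene decay table
#'
#' A measured decay curve: relative mRNA levels at fixed time points after
#' the interruption of transcription, normalized to 1 at \eqn{t = 0}. The
#' canonical grid is 0, 5, 10, 15, 20, 30, 40, 50, 60 min, but any strictly
#' increasing grid starting at 0 is accepted.
#'
#' @param gene_id identifier.
#' @param times time points (min), strictly increasing, starting at 0.
#' @param levels relative levels; `levels[1]` must equal 1 within
#'   `renormalize_tol` (then the row is renormalized with a warning) or the
#'   table is rejected.
#' @param renormalize_tol tolerated deviation of the t=0 level from 1
#'   (default 2%).
#' @return object of class `"decay_table"`.
#' @export
decay_table <- function(gene_id, times, levels, renormalize_tol = 0.02) {
  times <- as.numeric(times)
  levels <- as.numeric(levels)
  if (length(times) != length(levels))
    stop("`times` and `levels` must have equal length")
  if (anyNA(times) || anyNA(levels) || any(!is.finite(levels)))
    stop("times and levels must be finite numbers")
  if (is.unsorted(times, strictly = TRUE))
    stop("time points must be strictly increasing (no duplicates)")
  if (times[1] != 0) stop("the first time point must be t = 0")
  if (abs(levels[1] - 1) > renormalize_tol)
    stop("level at t = 0 is ", levels[1], "; more than ",
         renormalize_tol * 100, "% away from 1")
  if (levels[1] != 1) {
    warning("gene ", gene_id, ": level at t = 0 is ", levels[1],
            "; renormalizing to 1")
    levels <- levels / levels[1]
  }
  structure(list(gene_id = as.character(gene_id), times = times,
                 levels = levels),
            class = "decay_table")
}

#' @export
print.decay_table <- function(x, ...) {
  cat("Decay table for gene", x$gene_id, "\n")
  print(stats::setNames(x$levels, paste0("t", x$times)))
  invisible(x)
}

#' Residual sum of squares of a pattern against a decay table
#'
#' \eqn{RSS = \sum_j (\mathrm{level}_j - N_{rel}(t_j))^2} on the linear
#' scale of the relative levels (no weights, no log transform).
#'
#' @param table a [decay_table()].
#' @param pattern a `"decay_pattern"` (or any object with a `value` function).
#' @return the RSS (dimensionless).
#' @export
rss <- function(table, pattern) {
  stopifnot(inherits(table, "decay_table"))
  sum((table$levels - pattern$value(table$times))^2)
}

# ---- internal fitting machinery -------------------------------------------

variant_category <- c(exponential = 0L, last_step = 1L, first_step = 2L)

# map optimizer coordinates (log10 space) to a lifetime object
theta_to_lifetime <- function(theta, variant, n, free_pre) {
  r <- 10^theta
  switch(variant,
    exponential = lifetime_exponential(r[1]),
    first_step  = lifetime_first_step(omega = r[1], delta1 = r[2] + r[3],
                                      delta2 = r[2]),
    last_step   = if (free_pre)
        lifetime_last_step(omega = r[1], delta_pre = r[2],
                           delta_last = r[2] + r[3], n = n)
      else
        lifetime_last_step(omega = r[1], delta_pre = 0, delta_last = r[2],
                           n = n)
  )
}

# deterministic multi-start grid (log10 of rates) + one data-driven start
variant_starts <- function(variant, free_pre, table, lb, ub) {
  g <- seq(-2.5, 0.3, length.out = 8)          # rates 0.0032 .. 2 /min
  rot <- function(k) g[((seq_along(g) + k - 1) %% length(g)) + 1]
  last <- length(table$times)
  d0 <- -log(max(table$levels[last], 1e-3)) / table$times[last]
  d0 <- log10(min(max(d0, 10^lb), 10^ub))
  starts <- switch(variant,
    exponential = lapply(c(g, d0), function(x) x),
    first_step  = c(mapply(function(a, b, c) c(a, b, c),
                           g, rot(3), rot(5), SIMPLIFY = FALSE),
                    list(c(d0, d0 - 0.7, d0))),
    last_step   = if (free_pre)
        c(mapply(function(a, b, c) c(a, b, c), g, rot(4), rot(2),
                 SIMPLIFY = FALSE),
          list(c(d0 + 0.6, d0 - 1, d0)))
      else
        c(mapply(function(a, b) c(a, b), g, rot(4), SIMPLIFY = FALSE),
          list(c(d0 + 0.6, d0)))
  )
  starts
}

variant_bounds <- function(variant, free_pre, lb, ub) {
  np <- switch(variant, exponential = 1L, first_step = 3L,
               last_step = if (free_pre) 3L else 2L)
  lower <- rep(lb, np)
  upper <- rep(ub, np)
  if (variant == "first_step" || (variant == "last_step" && free_pre)) {
    lower[3] <- -9       # rate difference may be arbitrarily small
  }
  list(lower = lower, upper = upper, np = np)
}

#' Fit one lifetime-model variant to a decay table
#'
#' Bounded nonlinear least squares of the steady-state decay pattern of the
#' chosen variant against the measured levels. Optimization runs in log10
#' rate space with `L-BFGS-B` from a deterministic grid of starting points
#' (plus one data-driven start), and the best local optimum is returned, so
#' repeated calls are reproducible without any random seed.
#'
#' Variants and their constraints:
#' \describe{
#'   \item{`exponential`}{one rate \eqn{\delta}; pattern
#'     \eqn{e^{-\delta t}}.}
#'   \item{`first_step`}{rates \eqn{\omega, \delta_1, \delta_2} with
#'     \eqn{\delta_1 \ge \delta_2} (decreasing hazard, fast-slow family).}
#'   \item{`last_step`}{rates \eqn{\omega, \delta_n} with
#'     \eqn{\delta_i = 0} for \eqn{i < n} (increasing hazard, slow-fast
#'     family); with `free_pre = TRUE` a third rate
#'     \eqn{\delta_{pre} < \delta_n} is fitted.}
#' }
#'
#' @param table a [decay_table()].
#' @param variant `"exponential"`, `"first_step"` or `"last_step"`.
#' @param n chain length for `last_step` (default 5).
#' @param free_pre fit a free pre-terminal degradation rate in `last_step`.
#' @param bounds length-2 numeric, lower/upper bound on every rate (1/min).
#' @return object of class `"fit_result"`: `gene_id`, `category`, `omega`,
#'   `delta1`, `delta2`, `rss`, `mean_lifetime`, `half_life`,
#'   `variant_used`, `n_used`, the fitted `lifetime`, and the input grid.
#' @export
fit_variant <- function(table, variant = c("exponential", "first_step",
                                           "last_step"),
                        n = 5, free_pre = FALSE, bounds = c(1e-6, 10)) {
  stopifnot(inherits(table, "decay_table"))
  variant <- match.arg(variant)
  lb <- log10(bounds[1]); ub <- log10(bounds[2])
  bd <- variant_bounds(variant, free_pre, lb, ub)
  if (length(table$times) < bd$np + 1L)
    stop("table has too few points (", length(table$times),
         ") to fit ", bd$np, " parameters")
  obj <- function(theta) {
    lt <- theta_to_lifetime(theta, variant, n, free_pre)
    sum((table$levels - lt$tail_integral(table$times) / lt$mean)^2)
  }
  best <- NULL
  for (st in variant_starts(variant, free_pre, table, lb, ub)) {
    st <- pmin(pmax(st, bd$lower), bd$upper)
    fit <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = bd$lower,
                   upper = bd$upper,
                   control = list(maxit = 500, factr = 1e2,
                                  ndeps = rep(1e-7, bd$np))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("optimizer failed on all starting points for ",
                          variant, " fit of gene ", table$gene_id)
  lt <- theta_to_lifetime(best$par, variant, n, free_pre)
  r <- 10^best$par
  pars <- switch(variant,
    exponential = c(omega = NA_real_, delta1 = r[1], delta2 = NA_real_),
    first_step  = c(omega = r[1], delta1 = r[2] + r[3], delta2 = r[2]),
    last_step   = if (free_pre)
        c(omega = r[1], delta1 = r[2], delta2 = r[2] + r[3])
      else
        c(omega = r[1], delta1 = 0, delta2 = r[2])
  )
  structure(list(gene_id = table$gene_id,
                 category = variant_category[[variant]],
                 omega = unname(pars["omega"]),
                 delta1 = unname(pars["delta1"]),
                 delta2 = unname(pars["delta2"]),
                 rss = best$value,
                 mean_lifetime = lt$mean,
                 half_life = pattern_half_life(steady_state_pattern(lt)),
                 variant_used = variant,
                 n_used = if (variant == "last_step") as.integer(n) else 1L,
                 lifetime = lt,
                 times = table$times, levels = table$levels),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Fit for gene %s: %s (category %d)\n  rss = %.3g, <U> = %.4g min, t1/2 = %.4g min\n",
    x$gene_id, x$variant_used, x$category, x$rss, x$mean_lifetime,
    x$half_life))
  cat("  rates [1/min]: omega =", format(x$omega, digits = 4),
      "delta1 =", format(x$delta1, digits = 4),
      "delta2 =", format(x$delta2, digits = 4), "\n")
  invisible(x)
}

#' Fit all model variants and classify a decay curve
#'
#' Fits the one-parameter exponential model and both non-exponential
#' variants, then applies the 10% rule: the best non-exponential fit is
#' accepted only if it improves the RSS by at least
#' `config$rss_improvement_threshold` (default 10%) over the exponential
#' fit; otherwise the curve is called genuinely exponential. Categories:
#' 0 = exponential, 1 = slow-fast (`last_step`), 2 = fast-slow
#' (`first_step`). RSS ties within 1e-12 go to the model with fewer
#' parameters.
#'
#' @param table a [decay_table()].
#' @param config a [decay_config()].
#' @return a `"fit_result"`, with extra fields `rss_exponential` and
#'   `improvement` (fractional RSS reduction of the winning non-exponential
#'   fit, `NA` if no non-exponential fit converged) and `warning_flag`.
#' @export
select_and_classify <- function(table, config = decay_config()) {
  stopifnot(inherits(table, "decay_table"))
  f_exp <- fit_variant(table, "exponential", bounds = config$bounds)
  f_ne <- list()
  for (v in c("last_step", "first_step")) {   # fewer-parameter variant first: ties
                                              # resolve toward it via which.min
    f <- tryCatch(
      fit_variant(table, v, n = config$n_states,
                  free_pre = config$last_step_free_pre,
                  bounds = config$bounds),
      error = function(e) NULL)
    if (!is.null(f)) f_ne[[v]] <- f
  }
  warn <- length(f_ne) < 2L
  if (length(f_ne) == 0L) {
    out <- f_exp
    out$improvement <- NA_real_
  } else {
    rsses <- vapply(f_ne, `[[`, numeric(1), "rss")
    best <- f_ne[[which.min(rsses)]]
    improvement <- 1 - best$rss / f_exp$rss
    tie <- abs(best$rss - f_exp$rss) <= 1e-12
    out <- if (!tie && best$rss <= (1 - config$rss_improvement_threshold) *
                 f_exp$rss) best else f_exp
    out$improvement <- improvement
  }
  out$rss_exponential <- f_exp$rss
  out$warning_flag <- warn
  if (warn) warning("gene ", table$gene_id,
                    ": not all non-exponential fits converged")
  out
}

#' Fit and classify a collection of decay tables
#'
#' Applies [select_and_classify()] to every table, collecting per-gene
#' failures instead of aborting, and summarizes category counts and the RSS
#' distribution. Deterministic: the multi-start grid is fixed.
#'
#' @param tables list of [decay_table()] objects.
#' @param config a [decay_config()].
#' @return object of class `"batch_fit"`: `results` (list of
#'   `"fit_result"`), `failures` (named list of error messages), and
#'   `summary` (category counts and RSS quantiles).
#' @export
batch_fit <- function(tables, config = decay_config()) {
  stopifnot(length(tables) >= 1L)
  results <- list(); failures <- list()
  for (tb in tables) {
    r <- tryCatch(select_and_classify(tb, config), error = function(e) e)
    if (inherits(r, "error")) failures[[tb$gene_id]] <- conditionMessage(r)
    else results[[tb$gene_id]] <- r
  }
  cats <- vapply(results, `[[`, integer(1), "category")
  rsses <- vapply(results, `[[`, numeric(1), "rss")
  summary <- list(
    n = length(tables),
    n_fitted = length(results),
    category_counts = c("0_exponential" = sum(cats == 0L),
                        "1_slow_fast" = sum(cats == 1L),
                        "2_fast_slow" = sum(cats == 2L)),
    rss_quantiles = if (length(rsses))
      stats::quantile(rsses, c(0, 0.25, 0.5, 0.75, 1)) else NULL,
    frac_rss_below = if (length(rsses))
      mean(rsses < config$rss_accuracy_threshold) else NA_real_)
  structure(list(results = results, failures = failures, summary = summary,
                 config = config),
            class = "batch_fit")
}

#' @export
print.batch_fit <- function(x, ...) {
  s <- x$summary
  cat("Batch fit of", s$n, "decay tables (", s$n_fitted, "fitted,",
      length(x$failures), "failed )\n")
  cat("  categories:", paste(names(s$category_counts), s$category_counts,
                             sep = " = ", collapse = ", "), "\n")
  if (!is.null(s$rss_quantiles)) {
    cat("  RSS quartiles:", format(s$rss_quantiles, digits = 3), "\n")
    cat(sprintf("  fraction with RSS < %g: %.1f%%\n",
                x$config$rss_accuracy_threshold, 100 * s$frac_rss_below))
  }
  invisible(x)
}
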