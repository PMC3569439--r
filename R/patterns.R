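#' Decay pattern after transcription stop (steady state)
#'
#' Transforms a lifetime distribution into the observable relative mRNA
#' number \eqn{N_{rel}(\Delta t)} after transcription is interrupted in a
#' population at steady state. Because molecules of all ages are present at
#' the moment of the stop,
#' \deqn{N_{rel}(\Delta t) = \frac{1}{\langle U\rangle}
#'       \int_{\Delta t}^{\infty} S(u)\, du,}
#' where \eqn{S} is the survival function of the lifetime. The pattern starts
#' at 1, decreases, and is always convex — the model-free "bona fide"
#' criterion testable on data with [check_bona_fide()].
#'
#' @param lt a [lifetime_distribution()] with finite mean.
#' @return object of class `"decay_pattern"` with fields `value` (vectorized
#'   function of the delay, min), `mode = "steady_state"` and `source`.
#' @examples
#' p <- steady_state_pattern(lifetime_exponential(0.1))
#' p$value(10)  # exp(-1): exponential lifetimes are memoryless
#' @export
steady_state_pattern <- function(lt) {
  stopifnot(inherits(lt, "lifetime_distribution"))
  if (!is.finite(lt$mean)) stop("lifetime must have a finite mean")
  m <- lt$mean
  structure(list(value = function(dt) lt$tail_integral(dt) / m,
                 mode = "steady_state", source = lt),
            class = "decay_pattern")
}

#' Decay pattern after a transcriptional pulse
#'
#' For a cohort of molecules labeled in a short transcriptional pulse all
#' molecules share the same age, and the relative number still present at
#' time `t` is simply the survival function: \eqn{N_{rel}(t) = S(t)}. Unlike
#' the steady-state pattern, a pulse pattern need not be convex.
#'
#' @param lt a [lifetime_distribution()].
#' @return a `"decay_pattern"` with `mode = "pulse"`.
#' @export
pulse_pattern <- function(lt) {
  stopifnot(inherits(lt, "lifetime_distribution"))
  structure(list(value = function(t) lt$survival(t),
                 mode = "pulse", source = lt),
            class = "decay_pattern")
}

#' @export
print.decay_pattern <- function(x, ...) {
  cat("Decay pattern (", x$mode, ") from lifetime model [",
      x$source$provenance, "]\n", sep = "")
  invisible(x)
}

#' Half-life of a decay pattern
#'
#' The delay at which the pattern crosses 1/2, located by bracketing and
#' bisection (to about 1e-8 min). For non-exponential lifetimes this is not
#' \eqn{\ln 2 \cdot \langle U\rangle}; an exponential fit to a fast-slow
#' pattern can overestimate the true half-life substantially.
#'
#' @param p a `"decay_pattern"`.
#' @param horizon maximal delay searched (min) before giving up.
#' @return the half-life in minutes.
#' @export
pattern_half_life <- function(p, horizon = 1e7) {
  stopifnot(inherits(p, "decay_pattern"))
  if (p$value(horizon) > 0.5)
    stop("pattern does not reach 1/2 within the search horizon of ",
         horizon, " min")
  hi <- min(max(p$source$mean, 1), horizon)
  while (p$value(hi) > 0.5) hi <- min(hi * 2, horizon)
  stats::uniroot(function(t) p$value(t) - 0.5, c(0, hi),
                 tol = 1e-10)$root
}

#' Bona-fide (monotonicity + convexity) check of a measured decay table
#'
#' A steady-state decay pattern must be monotonically decreasing and convex
#' for *any* degradation mechanism; measured curves violating this cannot be
#' explained by any lifetime distribution and typically reflect experimental
#' perturbation. The check is discrete: first differences of the levels must
#' not rise above `+tol`, and second difference quotients (differences of
#' slopes on the possibly non-uniform time grid) must not fall below `-tol`.
#'
#' @param table a [decay_table()], or anything with `times` and `levels`.
#' @param tol non-negative tolerance for the "nearly bona-fide" verdict;
#'   `strict_pass` always uses 0.
#' @return list of class `"bona_fide_check"`: `status` one of
#'   `"strict_pass"`, `"near_pass"`, `"fail"`, plus `diagnostics` listing
#'   offending intervals.
#' @examples
#' tb <- decay_table("g", c(0, 5, 10, 15), c(1, 0.8, 0.65, 0.55))
#' check_bona_fide(tb)$status   # strict_pass
#' @export
check_bona_fide <- function(table, tol = 0.05) {
  stopifnot(is.numeric(tol), length(tol) == 1L, tol >= 0)
  times <- table$times
  levels <- table$levels
  if (length(times) < 3L) stop("need at least 3 time points")
  if (is.unsorted(times, strictly = TRUE)) stop("time points must be strictly increasing")
  d1 <- diff(levels)
  slopes <- d1 / diff(times)
  d2q <- diff(slopes)
  viol <- function(tl) {
    mono <- which(d1 > tl)
    conv <- which(d2q < -tl)
    rbind(
      if (length(mono))
        data.frame(type = "non_monotone", from = times[mono],
                   to = times[mono + 1], amount = d1[mono]),
      if (length(conv))
        data.frame(type = "non_convex", from = times[conv],
                   to = times[conv + 2], amount = d2q[conv])
    )
  }
  strict <- viol(0)
  near <- viol(tol)
  status <- if (is.null(strict) || nrow(strict) == 0) "strict_pass"
            else if (is.null(near) || nrow(near) == 0) "near_pass"
            else "fail"
  diagnostics <- if (status == "fail") near else strict
  if (is.null(diagnostics))
    diagnostics <- data.frame(type = character(), from = numeric(),
                              to = numeric(), amount = numeric())
  structure(list(status = status, tol = tol, diagnostics = diagnostics),
            class = "bona_fide_check")
}

#' @export
print.bona_fide_check <- function(x, ...) {
  cat("bona-fide check:", x$status, "(tol =", x$tol, ")\n")
  if (nrow(x$diagnostics)) {
    cat("offending intervals:\n")
    print(x$diagnostics, row.names = FALSE)
  }
  invisible(x)
}
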