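#' Simulation configuration
#'
#' Settings for the stochastic single-molecule simulator: the decay chain,
#' Poisson transcription at rate `nu`, the experimental protocol
#' (transcription stop from steady state, or a pulse cohort), sampling times
#' and ensemble size. A seed is mandatory — there is no silent
#' nondeterminism.
#'
#' @param chain a [decay_chain()], or `NULL` when the config is only used
#'   for [make_decay_tables()] (which takes its models from the truth
#'   table).
#' @param nu transcription rate (1/min); for the pulse protocol it is the
#'   mean cohort size per cell (molecules labeled in the pulse).
#' @param protocol `"steady_stop"` or `"pulse"`.
#' @param sample_times delays (min) at which counts are recorded; default is
#'   the canonical 9-point decay-assay grid.
#' @param n_cells number of replicate cells.
#' @param seed integer seed.
#' @param t_equilibrate burn-in time before the stop (min); default
#'   `20 * mean lifetime`, with a warning below that.
#' @param noise_sigma additive measurement noise used by
#'   [make_decay_tables()] (relative-level units); must be `< 0.3`.
#' @param init `"burn_in"` (simulate births over `t_equilibrate`) or
#'   `"stationary"` (exact stationary construction: Poisson count with mean
#'   \eqn{\nu\langle U\rangle} and residual lifetimes drawn from the
#'   stationary residual law). Both sample the same ensemble law.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(chain = NULL, nu = 1,
                       protocol = c("steady_stop", "pulse"),
                       sample_times = c(0, 5, 10, 15, 20, 30, 40, 50, 60),
                       n_cells = 1000, seed,
                       t_equilibrate = NULL, noise_sigma = 0.02,
                       init = c("burn_in", "stationary")) {
  stopifnot(is.null(chain) || inherits(chain, "decay_chain"),
            nu > 0, n_cells >= 1)
  protocol <- match.arg(protocol)
  init <- match.arg(init)
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` is mandatory")
  if (noise_sigma < 0 || noise_sigma >= 0.3)
    stop("`noise_sigma` must be in [0, 0.3): larger noise destroys the ",
         "shape of the decay curve")
  if (is.unsorted(sample_times) || any(sample_times < 0))
    stop("`sample_times` must be non-decreasing and non-negative")
  mean_u <- if (is.null(chain)) NA_real_ else chain_moment(chain, 1)
  if (is.null(t_equilibrate)) t_equilibrate <- 20 * mean_u
  if (!is.null(chain) && protocol == "steady_stop" &&
      t_equilibrate < 20 * mean_u)
    warning("t_equilibrate < 20 mean lifetimes; the pre-stop population ",
            "may not be stationary")
  structure(list(chain = chain, nu = nu, protocol = protocol,
                 sample_times = as.numeric(sample_times),
                 n_cells = as.integer(n_cells), seed = as.integer(seed),
                 t_equilibrate = t_equilibrate, noise_sigma = noise_sigma,
                 init = init, mean_lifetime = mean_u),
            class = "sim_config")
}

#' Sample single-molecule lifetimes from a decay chain
#'
#' Exact stochastic simulation by competing exponential clocks: in state
#' \eqn{i} the molecule waits \eqn{Exp(\omega_i + \delta_i)} and then either
#' degrades (probability \eqn{\delta_i/(\omega_i+\delta_i)}) or moves to
#' state \eqn{i+1}. The total time to absorption is returned. Uses R's
#' global RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param chain a [decay_chain()].
#' @param n number of molecules.
#' @return numeric vector of `n` lifetimes (min).
#' @export
sample_lifetime <- function(chain, n = 1) {
  stopifnot(inherits(chain, "decay_chain"), n >= 0)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  omega_ext <- c(chain$omega, 0)
  state <- if (chain$n == 1L) rep(1L, n)
           else sample.int(chain$n, n, replace = TRUE,
                           prob = chain$initial_state)
  life <- numeric(n)
  done <- rep(FALSE, n)
  for (k in seq_len(chain$n)) {
    idx <- which(!done & state == k)
    if (!length(idx)) next
    a <- omega_ext[k] + chain$delta[k]
    life[idx] <- life[idx] + stats::rexp(length(idx), a)
    absorbed <- stats::runif(length(idx)) < chain$delta[k] / a
    done[idx[absorbed]] <- TRUE
    state[idx[!absorbed]] <- k + 1L
  }
  # certain absorption is enforced by decay_chain(), so nothing survives the loop
  life
}

# residual death times under the stationary law: survival of the residual is
# G(r)/<U>; inverted on a dense grid (statistical accuracy, not 1e-10 roots)
sample_stationary_residuals <- function(lt, n) {
  if (n == 0L) return(numeric(0))
  hi <- lt$mean
  while (lt$tail_integral(hi) / lt$mean > 1e-9) hi <- hi * 2
  r <- seq(0, hi, length.out = 4096)
  cdf <- 1 - lt$tail_integral(r) / lt$mean
  inv <- stats::approxfun(cdf, r, rule = 2, ties = "ordered")
  inv(stats::runif(n))
}

#' Run a stochastic decay experiment
#'
#' Simulates an ensemble of cells and returns the per-cell molecule counts
#' at each sampling time.
#'
#' For `protocol = "steady_stop"` the population is brought to steady state
#' (explicit burn-in of Poisson births, or the exact stationary
#' construction, per `cfg$init`), transcription is stopped at time 0, and
#' survivors are counted at each delay. For `protocol = "pulse"` each cell
#' receives a Poisson(`nu`) cohort born at time 0.
#'
#' @param cfg a [sim_config()].
#' @return object of class `"decay_ensemble"`: integer matrix `counts`
#'   (`n_cells` x `length(sample_times)`), `sample_times`, and the config.
#'   Deterministic given `cfg$seed`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$chain)) stop("`cfg` has no decay chain")
  set.seed(cfg$seed)
  nc <- cfg$n_cells
  st <- cfg$sample_times
  if (cfg$protocol == "steady_stop") {
    if (cfg$init == "burn_in") {
      teq <- cfg$t_equilibrate
      n_tot <- stats::rpois(1, nc * cfg$nu * teq)
      cell <- sample.int(nc, n_tot, replace = TRUE)
      birth <- stats::runif(n_tot, 0, teq)
      death <- birth + sample_lifetime(cfg$chain, n_tot) - teq
    } else {
      lt <- lifetime_from_chain(cfg$chain)
      per_cell <- stats::rpois(nc, cfg$nu * lt$mean)
      cell <- rep.int(seq_len(nc), per_cell)
      death <- sample_stationary_residuals(lt, length(cell))
    }
  } else {
    per_cell <- stats::rpois(nc, cfg$nu)
    cell <- rep.int(seq_len(nc), per_cell)
    death <- sample_lifetime(cfg$chain, length(cell))
  }
  counts <- vapply(st, function(dt) tabulate(cell[death > dt], nbins = nc),
                   integer(nc))
  dimnames(counts) <- list(NULL, paste0("t", st))
  structure(list(counts = counts, sample_times = st, config = cfg),
            class = "decay_ensemble")
}

#' @export
print.decay_ensemble <- function(x, ...) {
  cat("Decay ensemble:", nrow(x$counts), "cells,",
      length(x$sample_times), "sample times (protocol:",
      x$config$protocol, ")\n")
  cat("  mean counts:", format(colMeans(x$counts), digits = 4), "\n")
  invisible(x)
}

#' Ensemble mean decay curve
#'
#' Mean count at each sampling time divided by the mean at the first time
#' point — the Monte-Carlo estimate of the decay pattern.
#'
#' @param ens a `"decay_ensemble"`.
#' @return named numeric vector of relative levels.
#' @export
ensemble_pattern <- function(ens) {
  stopifnot(inherits(ens, "decay_ensemble"))
  m <- colMeans(ens$counts)
  m / m[1]
}

#' Generate synthetic decay tables with known ground truth
#'
#' Builds Table-style fixtures for closed-loop tests of the fitting
#' pipeline: for each gene the analytic steady-state pattern of its true
#' model is evaluated on the sampling grid, additive Gaussian measurement
#' noise (sd `cfg$noise_sigma`, redrawn where a level would be non-positive)
#' is applied, and the curve is renormalized to 1 at t = 0.
#'
#' @param cfg a [sim_config()] (uses `sample_times`, `noise_sigma`, `seed`).
#' @param truth data frame with columns `gene_id`, `variant`
#'   (`"exponential"`, `"first_step"`, `"last_step"`), `omega`, `delta1`,
#'   `delta2`, and optionally `n` (chain length for `last_step`, default 5).
#'   For `exponential`, `delta1` is the rate. For `last_step`, `delta1` is
#'   the pre-terminal and `delta2` the terminal degradation rate.
#' @return list with `tables` (list of [decay_table()]) and `manifest`
#'   (the truth plus the analytic mean lifetime and half-life per gene).
#' @export
make_decay_tables <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(truth),
            all(c("gene_id", "variant", "omega", "delta1", "delta2") %in%
                  names(truth)))
  set.seed(cfg$seed)
  times <- cfg$sample_times
  sigma <- cfg$noise_sigma
  nvec <- if ("n" %in% names(truth)) truth$n else rep(5L, nrow(truth))
  tables <- vector("list", nrow(truth))
  mean_lt <- half <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    lt <- switch(as.character(truth$variant[i]),
      exponential = lifetime_exponential(truth$delta1[i]),
      first_step = lifetime_first_step(truth$omega[i], truth$delta1[i],
                                       truth$delta2[i]),
      last_step = lifetime_last_step(truth$omega[i], truth$delta1[i],
                                     truth$delta2[i], n = nvec[i]),
      stop("unknown variant: ", truth$variant[i]))
    p <- steady_state_pattern(lt)
    v <- p$value(times)
    if (sigma > 0) {
      lv <- v + stats::rnorm(length(v), 0, sigma)
      while (any(lv <= 0)) {                  # truncate: levels stay positive
        redo <- lv <= 0
        lv[redo] <- v[redo] + stats::rnorm(sum(redo), 0, sigma)
      }
    } else lv <- v
    lv <- lv / lv[1]
    tables[[i]] <- decay_table(truth$gene_id[i], times, lv)
    mean_lt[i] <- lt$mean
    half[i] <- pattern_half_life(p)
  }
  manifest <- cbind(truth, mean_lifetime = mean_lt, half_life = half)
  list(tables = tables, manifest = manifest)
}
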