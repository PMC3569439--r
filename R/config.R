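#' Run configuration for the fitting/classification pipeline
#'
#' Bundles the tunable thresholds of the pipeline. Defaults follow the
#' reference analysis: a non-exponential model must improve the RSS by at
#' least 10% to displace the exponential fit; a curve counts as "fitted
#' accurately" when its RSS is below 0.01; the multi-step chain has 5
#' states; curves within 0.05 of discrete monotonicity/convexity are
#' "nearly bona-fide".
#'
#' @param bona_fide_tol tolerance of [check_bona_fide()] (level units).
#' @param rss_improvement_threshold fractional RSS improvement required to
#'   accept a non-exponential model, in (0, 1).
#' @param rss_accuracy_threshold RSS below which a fit is called accurate,
#'   in (0, 1).
#' @param n_states chain length of the `last_step` variant, `>= 2`.
#' @param last_step_free_pre also fit a pre-terminal degradation rate.
#' @param bounds lower/upper bound on every fitted rate (1/min).
#' @param seed integer seed used by simulation helpers.
#' @return object of class `"decay_config"`.
#' @export
decay_config <- function(bona_fide_tol = 0.05,
                         rss_improvement_threshold = 0.10,
                         rss_accuracy_threshold = 0.01,
                         n_states = 5,
                         last_step_free_pre = FALSE,
                         bounds = c(1e-6, 10),
                         seed = 1L) {
  stopifnot(bona_fide_tol >= 0,
            rss_improvement_threshold > 0, rss_improvement_threshold < 1,
            rss_accuracy_threshold > 0, rss_accuracy_threshold < 1,
            n_states >= 2, length(bounds) == 2L, bounds[1] > 0,
            bounds[1] < bounds[2])
  structure(list(bona_fide_tol = bona_fide_tol,
                 rss_improvement_threshold = rss_improvement_threshold,
                 rss_accuracy_threshold = rss_accuracy_threshold,
                 n_states = as.integer(n_states),
                 last_step_free_pre = isTRUE(last_step_free_pre),
                 bounds = as.numeric(bounds),
                 seed = as.integer(seed)),
            class = "decay_config")
}

#' Save / load a run configuration
#'
#' JSON round-trip: `load_config(save_config(cfg, path))` reproduces `cfg`.
#'
#' @param config a [decay_config()].
#' @param path file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns a
#'   [decay_config()].
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "decay_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  decay_config(bona_fide_tol = x$bona_fide_tol,
               rss_improvement_threshold = x$rss_improvement_threshold,
               rss_accuracy_threshold = x$rss_accuracy_threshold,
               n_states = x$n_states,
               last_step_free_pre = x$last_step_free_pre,
               bounds = x$bounds,
               seed = x$seed)
}
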