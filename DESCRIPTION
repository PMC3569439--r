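Package: decaychain
Title: Phase-Type Lifetime Models for Non-Exponential mRNA Decay
Version: 0.1.0
Authors@R:
    person("decaychain", "maintainers", email = "maintainers@decaychain.org",
           role = c("aut", "cre"))
Description: Models mRNA degradation as an absorbing continuous-time Markov
    chain of biochemical intermediates and links the resulting phase-type
    single-molecule lifetime distribution to the population-level decay
    pattern observed after transcription shut-off or a transcriptional
    pulse. Provides closed-form lifetime models (single rate-limiting step,
    first-step variant, last-step variant), the lifetime-to-decay-pattern
    transform with its convexity ('bona fide') criterion, age-dependent
    degradation rates (hazards), residual lifetimes and residual protein
    synthesis capacity, Poisson copy-number laws at steady state and after
    transcription stop, a stochastic single-molecule simulator, and a
    genome-wide fitting and classification pipeline with a command-line
    interface for decay tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
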