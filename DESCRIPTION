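Package: latentRL
Title: Latent Reinforcement Learning Decomposition of Vocal Pitch Variability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a latent reinforcement-learning state-space model to
    trial-by-trial vocal pitch data from operant conditioning experiments
    (e.g. white-noise pitch conditioning in songbirds and humans). Pitch is
    additively decomposed into iid Gaussian motor exploration, a
    reward-learned bias that performs a leaky correlation of exploration
    with reward, and non-reinforced repertoire components (slow colored
    drift, piecewise-linear circadian pattern, and singing-history offsets).
    Parameters are estimated by expectation maximization on a linear
    Gaussian state-space formulation with time-varying transitions and
    inputs. Includes self-consistency diagnostics based on lagged mutual
    average information with white-noise surrogate normalization, a
    generative experiment simulator with adaptive threshold policies, and a
    sliding-window pitch-step detector with an equality-of-proportions test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
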