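Package: actionddm
Title: Response-Outcome Reinforcement Learning Drift Diffusion Modeling of the Probabilistic Reward Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling behavior on the Probabilistic Reward Task (PRT) with a
    reinforcement-learning drift diffusion model in which delta-rule response-outcome
    values modulate both the trial-wise drift rate and the starting-point bias of a
    Wiener diffusion decision process. Provides task-schedule generation and quality
    control for PRT trial tables, a Wiener first-passage-time likelihood with
    trial-varying drift and starting point, forward simulation of single subjects and
    synthetic cohorts with group-level parameter distributions and injected group
    effects, hierarchical Bayesian estimation by adaptive MCMC with Gelman-Rubin
    convergence diagnostics and WAIC model comparison across a lattice of lesioned
    model variants, signal-detection performance statistics (response bias,
    discriminability), split-half reliability (Spearman-Brown, intraclass
    correlation), posterior predictive checks, and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
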