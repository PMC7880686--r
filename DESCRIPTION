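Package: rleam
Title: Reinforcement-Learning Evidence-Accumulation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint models of instrumental learning and speeded decision making
    that couple delta-rule value learning to evidence-accumulation choice
    architectures: the diffusion decision model (including between-trial
    variability variants and a non-linear value link), the racing diffusion,
    the advantage racing diffusion, and a multi-alternative advantage race
    with a Win-All stopping rule. Provides exact trial-level likelihoods built
    on Wald (inverse-Gaussian) first-passage distributions, closed-loop
    simulators for four instrumental-learning paradigms (including
    speed-accuracy cueing with deadlines, mid-block reward reversals, and
    three-alternative choice), hierarchical Bayesian estimation by
    differential-evolution MCMC with Gelman-Rubin diagnostics and BPIC model
    comparison, and an assessment layer for posterior-predictive checks,
    reversal-aligned summaries, exclusion screening, and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    statmod,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    coda,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
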