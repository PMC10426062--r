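Package: slbandit
Title: Evolution of Social Learning Under Uncertainty on a Multi-Armed Bandit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolutionary agent-based simulations of a heritable social-learning
    trait in a population of reinforcement learners facing a B-armed Bernoulli
    bandit. Agents choose behaviours by a softmax (Boltzmann) decision rule over
    running-mean payoff estimates; social learners additionally inherit a
    teacher's payoff beliefs through payoff-biased vertical/oblique
    transmission. The package exposes the environment (arm count, payoff
    probabilities, stochastic change of the optimal arm, effective lifespan),
    the agent cognition, single evolutionary trials run to fixation of the
    social-learning trait, and ensemble machinery: parameter sweeps, fixation
    frequencies, generations to fixation, normalized payoffs, the
    social-learning ceiling, homogeneous-population payoff references and
    geometric moving-average payoff series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
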