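# slbandit

Evolutionary agent-based simulations of **social learning under
uncertainty**. The package asks a classic question in cultural evolution —
when does copying others beat learning on your own? — in a world where
individual learning is genuinely hard: a `B`-armed Bernoulli bandit whose
optimal behaviour can change between generations.

It is aimed at cultural-evolution and behavioural-ecology modellers who want
a reproducible, testable implementation of payoff-biased vertical/oblique
transmission coupled to a realistic reinforcement-learning agent, with
ensemble machinery for fixation statistics and parameter sweeps.

## The model

A population of `N` haploid agents carries one evolving binary trait,
social learning. Each generation:

* Every agent gets `L` time steps (the *effective lifespan*). At each step,
  agent *i* performs arm *b* with softmax probability
  P(b) ∝ exp(β·π̂<sub>ib</sub>), collects a Bernoulli payoff — probability
  π<sub>high</sub> on the optimal arm, π<sub>low</sub> elsewhere — and
  updates its running-mean estimate π̂<sub>ib</sub> with post-increment
  count c<sub>ib</sub>:
  π̂<sub>ib</sub> ← π̂<sub>ib</sub> + (payoff − π̂<sub>ib</sub>) / c<sub>ib</sub>.
* `N` parents are then drawn with replacement, proportionally to lifetime
  net payoff. Children inherit the trait without mutation. A social-learner
  child samples `N_T` prospective teachers without replacement, adopts the
  best-paying one's estimates, and keeps a single pseudo-observation
  (c<sub>ib</sub> = 1) per transmitted arm; asocial children start naive.
* After die-off, the optimal arm changes with probability `u`, always to a
  different arm.

Trials run until the trait fixes (all-social or all-asocial). Four
uncertainty dimensions are exposed: environmental variability `u`,
selection-set size `B`, payoff ambiguity π<sub>high</sub> − π<sub>low</sub>,
and effective lifespan `L`. Headline outcome measures are the
social-learning fixation frequency ρ̂, generations to fixation, normalized
payoffs, and the *social-learning ceiling* u<sub>c</sub> — the smallest `u`
at which social learning fixates in fewer than 1% of trials.

## Worked example

```r
library(slbandit)

cfg <- sim_config(
  N = 100,
  env = env_config(B = 10, pi_low = 0.1, u = 0.2, L = 10),
  cognition = cognition_config(beta = 10, N_T = 5),
  seed = 42, record_timeseries = TRUE
)
run_trial(cfg)
#> <trial_result> social_fixation after 10 generation(s); final mean normalized payoff 0.8640
```

With ten behaviours, a changing environment (`u = 0.2`) and ten learning
opportunities per lifetime, this run fixed at all-social learners after 10
generations, by which point the average agent was earning 0.864 of the
maximum — close to the optimal-arm rate π<sub>high</sub> = 0.9, i.e. the
population had found and was exploiting the optimal behaviour.

```r
ens <- run_ensemble(cfg, n_trials = 100, base_seed = 1)
ens[, c("rho_hat", "mean_generations", "mean_normalized_payoff")]
#> # A tibble: 1 × 3
#>   rho_hat mean_generations mean_normalized_payoff
#>     <dbl>            <dbl>                  <dbl>
#> 1       1             9.79                  0.807
```

Across 100 independent trials at this setting, social learning fixed every
time (ρ̂ = 1), on average within ~10 generations. `run_sweep(sweep_spec())`
runs the full factorial grid over `(u, B, pi_low, L)` and returns a tidy
tibble (optionally written to CSV with a JSON manifest);
`social_learning_ceiling()`, `homogeneous_reference()` and
`geometric_moving_average()` compute the derived measures.

A thin command-line wrapper ships at
`system.file("cli", "slbandit.R", package = "slbandit")` with `sweep`,
`trial`, `ceiling` and `reference` subcommands driven by a YAML config.

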