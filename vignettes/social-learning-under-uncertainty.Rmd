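---
title: "Modelling the evolution of social learning under uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of social learning under uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`slbandit` simulates the evolution of a single heritable, binary trait —
social learning — in a finite population of `N` agents that live in a
`B`-armed Bernoulli bandit world. One arm (the *optimal behaviour*) pays 1
with probability $\pi_{high}$; the other $B - 1$ arms pay 1 with probability
$\pi_{low} \le \pi_{high}$. Four parameters operationalize four distinct
sources of uncertainty:

* **Environmental variability** `u`: at each generation boundary a new
  optimal arm is drawn with probability `u`, uniformly from the $B - 1$
  non-current arms (the current optimal is always excluded, so a "change"
  always changes something).
* **Selection-set size** `B`: more arms means more ways to be wrong.
* **Payoff ambiguity** $\pi_{high} - \pi_{low}$: the smaller the gap, the
  noisier the signal distinguishing the optimal behaviour. We follow the
  convention of fixing $\pi_{high} = 0.9$ and varying $\pi_{low}$.
* **Effective lifespan** `L`: the number of within-generation opportunities
  each agent has to act and learn individually.

### Individual learning

Every agent — social learner or not — learns by trial and error. Agent $i$
keeps a running mean payoff estimate $\hat\pi_{ib}$ and an observation count
$c_{ib}$ for each arm $b$, both initially zero. At each of its `L` time
steps the agent performs arm $b$ with softmax (Boltzmann) probability

$$P(b) = \frac{\exp(\beta\,\hat\pi_{ib})}{\sum_{b'}\exp(\beta\,\hat\pi_{ib'})},$$

collects a Bernoulli payoff, increments $c_{ib}$, and then updates the
estimate by one running-mean step using the *post-increment* count:

$$\hat\pi_{ib} \leftarrow \hat\pi_{ib} + \frac{\text{payoff} - \hat\pi_{ib}}{c_{ib}}.$$

This ordering makes the estimate after $k$ observations exactly the
arithmetic mean of those $k$ payoffs (a property the test suite checks to
$10^{-12}$ against a brute-force mean). The greediness $\beta$ (default 10)
sets the exploration–exploitation balance: $\beta = 0$ is uniform random
choice, large $\beta$ is near-greedy.

### Social transmission and reproduction

Between generations, events happen in exactly this order:

1. **Reproduction.** `N` parents are drawn with replacement, each draw
   selecting agent $i$ with probability $\pi_i / \sum_j \pi_j$, where
   $\pi_i$ is lifetime net payoff. If every payoff is zero (possible when
   $\pi_{low} = 0$ and `L` is small) the draw falls back to uniform, since
   proportional selection is undefined at $0/0$.
2. **Transmission.** Each child inherits its parent's trait without
   mutation. A social-learner child samples `N_T` (default 5) prospective
   teachers uniformly *without replacement* from the whole parent generation
   — possibly including its own parent, so transmission is vertical and/or
   oblique — and adopts the estimates of the best-paying one, ties broken
   uniformly. Transmitted counts are clamped: $c_{ib} = 1$ where the teacher
   had at least one observation, else 0. The child therefore treats the
   teacher's entire experience of an arm as a single observation, which
   keeps social learners flexible: their next individual observation of a
   transmitted arm carries weight 1/2. Asocial children start naive.
3. **Die-off** of the parent generation.
4. **Environmental change** with probability `u`.

Fixation is checked on the child generation immediately after transmission,
before those children live; the generation counter counts completed (lived)
generations. Trials that reach `max_generations` (default 10,000) without
fixing are reported as censored and excluded from fixation-frequency
numerator and denominator, with a loud warning when censoring exceeds 1% of
an ensemble.

## Outcome measures

* $\hat\rho$ — the social-learning fixation frequency across trials.
* Mean generations to fixation — an inverse measure of selection strength.
* Mean normalized payoff — the final lived generation's mean of
  `net_payoff / L`.
* The **social-learning ceiling** $u_c$ — the smallest grid value of `u` at
  which $\hat\rho < 0.01$. It is a literal minimum over grid points, not an
  interpolated crossing; when no grid point qualifies,
  `social_learning_ceiling()` returns `NA`, meaning the ceiling lies above
  the grid.
* `homogeneous_reference()` benchmarks all-social and all-asocial
  populations: with no mutation these compositions persist, so each trial
  runs a fixed 100 generations for payoffs to stabilize and the final
  generation's mean normalized payoff is averaged across trials.
* `geometric_moving_average()` (window 3 by default) smooths per-generation
  payoff series for diagnosing geometric-mean-fitness effects of runs of
  environmental change. It is applied to per-generation class means;
  generations where a learner class is empty yield `NA`, not zero.

## Defaults and study conditions

The package defaults encode the conditions of the headline experiments:
$\pi_{high} = 0.9$, $\beta = 10$, `N_T = 5`, `N = 100`, 1000 trials per
parameter combination, and sweep grids `u` in $\{0, 0.1, \ldots, 0.9\}$,
`B` in $\{2, 4, 10\}$, $\pi_{low}$ in $\{0.1, 0.45, 0.8\}$, `L` in
$\{1, 4, 8, 20\}$. Populations are initialized with each agent carrying the
social-learning trait independently with probability 1/2, and the first
generation's social learners are naive (there is no earlier generation to
learn from).

## Numerical and design choices

* **Vectorized engine.** Agents do not interact within a generation, so the
  within-generation loop is vectorized across agents one synchronous time
  step at a time; each agent still experiences exactly `L` independent
  choose–payoff–update cycles under the per-agent law. The test suite
  cross-checks the engine against the exported scalar operations.
* **Teacher draws.** Children choose teachers independently under an
  identical rule, so the engine draws each child's teacher i.i.d. from the
  exact closed-form distribution induced by best-of-`N_T` sampling
  (`teacher_distribution()`); a test verifies the closed form against
  exhaustive subset enumeration and the sampling rule itself.
* **Softmax stability.** Probabilities are computed with an exponent shift,
  so the function is shift-invariant and overflow-safe for any finite
  `beta`; a single global shift is used when the exponent spread is small
  (it cancels row-wise in the normalization) and a per-row shift otherwise.
* **Tie-breaks.** Teacher-payoff ties are uniform; softmax never needs a
  tie-break because sampling is by inverse CDF with the final cumulative
  bin pinned to 1.
* **Seeding.** A single master seed generates one sub-seed per trial (and
  per combination in sweeps) up front, so ensembles are reproducible and
  independent of evaluation order. `run_trial()` with a fixed seed is
  bit-reproducible.
* **Degenerate inputs.** `B = 1` is allowed for testing closed-form payoff
  predictions but rejected together with `u > 0`; `N_T > N` is rejected
  because teachers are sampled without replacement.

## What the simulations do and do not emulate

All data are generated by the model itself; there is no empirical input.
The environment captures abrupt, memoryless change of a single optimal
behaviour with two payoff tiers. It does not emulate graded or
multi-tier payoff structures, payoff variance manipulations, spatial
structure, horizontal (within-generation) transmission, conformity, niche
construction, or trait mutation. Conclusions drawn from passing tests are
therefore about this idealized world: they show the implementation's
dynamics are correct and its qualitative responses to each uncertainty axis
are as theory predicts, not that real populations behave this way.

## Problem sizes in the test suite

The shipped tests run at desk scale: 100–200 trials per parameter
combination for directional and monotonicity checks (against pooled binomial
standard errors), 2000 trials for the neutral-drift oracle, 100 trials per
grid point for the social-learning ceiling, and 150–300 trials for
homogeneous references. Full-scale sweeps (1000 trials per combination, the
package default) reproduce the same patterns with tighter error bars and are
what `run_sweep()` performs when left at its defaults.

## Known limitations

* Generations-to-fixation averages are conditioned on fixation occurring;
  under very weak selection (high $\pi_{low}$, small `N`) censoring at
  `max_generations` can bias them low if the cap is set aggressively.
* The fixation-frequency denominator excludes censored trials, which is the
  honest choice but means $\hat\rho$ from heavily censored ensembles has a
  wider effective confidence band than `n_trials` suggests.
* In-process execution only; sweeps are embarrassingly parallel but the
  package does not schedule them across workers.

## A minimal session

```{r, eval = FALSE}
library(slbandit)

cfg <- sim_config(
  N = 100,
  env = env_config(B = 10, pi_low = 0.1, u = 0.2, L = 10),
  cognition = cognition_config(beta = 10, N_T = 5),
  seed = 42, record_timeseries = TRUE
)
trial <- run_trial(cfg)
trial
head(trial$timeseries)

# fixation frequency at one parameter combination
ens <- run_ensemble(cfg, n_trials = 100, base_seed = 1)
ens$rho_hat

# the ceiling for a large selection set
res <- ceiling_for_slice(u = seq(0.1, 0.6, 0.1), B = 10, pi_low = 0.1,
                         L = 10, n_trials = 100, base_seed = 1)
res$u_c
```
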