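#' Run an ensemble of trials for one parameter combination
#'
#' Repeats [run_trial()] `n_trials` times and aggregates the outcomes. Each
#' trial gets its own seed drawn reproducibly from `base_seed`, so the
#' ensemble is a pure function of `(cfg, n_trials, base_seed)` and trials are
#' independent of execution order.
#'
#' Censored trials (no fixation within `max_generations`) are excluded from
#' both the numerator and denominator of the fixation frequency and from the
#' generation and payoff averages; a warning is raised if more than 1% of
#' trials are censored.
#'
#' @param cfg A [sim_config()]; its `seed` field is ignored.
#' @param n_trials Number of independent trials, `>= 1`.
#' @param base_seed Integer master seed.
#' @return A one-row [tibble::tibble] with columns `n_trials`, `rho_hat`
#'   (social-learning fixation frequency among fixated trials),
#'   `mean_generations` (mean generations to fixation),
#'   `mean_normalized_payoff` (mean over fixated trials of the final
#'   generation's mean `net_payoff / L`), `n_social`, `n_asocial`,
#'   `n_censored`.
#' @export
run_ensemble <- function(cfg, n_trials = 1000, base_seed = 1) {
  stopifnot(inherits(cfg, "sim_config"), n_trials >= 1)
  seeds <- draw_trial_seeds(base_seed, n_trials)
  outcomes <- character(n_trials)
  gens <- integer(n_trials)
  payoff <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    cfg$seed <- seeds[k]
    r <- run_trial(cfg)
    outcomes[k] <- r$outcome
    gens[k] <- r$generations
    payoff[k] <- r$mean_normalized_payoff
  }
  summarize_outcomes(outcomes, gens, payoff, n_trials)
}

# Per-trial seeds derived from one master seed. Drawn in a fixed order from a
# dedicated RNG state so ensembles are reproducible and order-independent;
# seeds stay within the 32-bit integer range.
draw_trial_seeds <- function(base_seed, n) {
  state <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
  })
  set.seed(base_seed)
  sample.int(.Machine$integer.max, n)
}

summarize_outcomes <- function(outcomes, gens, payoff, n_trials) {
  fixed <- outcomes != "censored"
  n_social <- sum(outcomes == "social_fixation")
  n_asocial <- sum(outcomes == "asocial_fixation")
  n_censored <- sum(!fixed)
  if (n_censored > 0.01 * n_trials) {
    warning(sprintf(
      "%d of %d trials censored at the generation cap; aggregates use fixated trials only",
      n_censored, n_trials
    ))
  }
  tibble::tibble(
    n_trials = n_trials,
    rho_hat = if (any(fixed)) n_social / sum(fixed) else NA_real_,
    mean_generations = if (any(fixed)) mean(gens[fixed]) else NA_real_,
    mean_normalized_payoff =
      if (any(fixed)) mean(payoff[fixed], na.rm = TRUE) else NA_real_,
    n_social = n_social,
    n_asocial = n_asocial,
    n_censored = n_censored
  )
}

#' Social-learning ceiling
#'
#' The ceiling `u_c` is the smallest environmental-change rate on the grid at
#' which social learning fixated in fewer than `threshold` (default 1 in 100)
#' of trials. It is the literal minimum over qualifying grid points, not an
#' interpolated crossing.
#'
#' @param u Ascending grid of environmental-variability values.
#' @param rho_hat Social-learning fixation frequency at each grid point.
#' @param threshold Rarity threshold, default 0.01.
#' @return The ceiling `u_c`, or `NA_real_` when no grid point qualifies
#'   (the ceiling lies above the grid).
#' @examples
#' social_learning_ceiling(c(0.1, 0.2, 0.3, 0.4), c(0.9, 0.2, 0.005, 0))
#' @export
social_learning_ceiling <- function(u, rho_hat, threshold = 0.01) {
  if (length(u) == 0) stop("empty grid")
  stopifnot(length(u) == length(rho_hat), !is.unsorted(u),
            all(rho_hat >= 0 & rho_hat <= 1))
  hit <- which(rho_hat < threshold)
  if (length(hit) == 0) NA_real_ else u[min(hit)]
}

#' Mean payoff of a homogeneous reference population
#'
#' Benchmarks the payoff a population would earn if it were composed entirely
#' of social or entirely of asocial learners. With no mutation such
#' populations persist unchanged, so each trial runs for a fixed number of
#' generations (default 100, letting payoffs stabilize) rather than to
#' fixation, and the final generation's mean normalized payoff is averaged
#' across trials.
#'
#' @param cfg A [sim_config()]; its `seed` field is ignored.
#' @param trait `"social"` or `"asocial"`.
#' @param n_trials Number of independent trials.
#' @param base_seed Integer master seed.
#' @param generations Generations run per trial, default 100.
#' @return The mean over trials of the last generation's mean
#'   `net_payoff / L` across agents.
#' @export
homogeneous_reference <- function(cfg, trait = c("social", "asocial"),
                                  n_trials = 1000, base_seed = 1,
                                  generations = 100) {
  trait <- match.arg(trait)
  stopifnot(inherits(cfg, "sim_config"), generations >= 1)
  s_value <- if (trait == "social") 1L else 0L
  seeds <- draw_trial_seeds(base_seed, n_trials)
  final <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    set.seed(seeds[k])
    env <- init_environment(cfg$env)
    pop <- init_population(cfg$N, cfg$env$B, rep(s_value, cfg$N))
    for (g in seq_len(generations)) {
      pop <- run_generation(pop, env, cfg)
      if (g < generations) {
        stepped <- step_intergenerational(pop, env, cfg)
        pop <- stepped$pop
        env <- stepped$env
      }
    }
    final[k] <- mean(pop$net) / cfg$env$L
  }
  mean(final)
}

#' Geometric moving average of a payoff series
#'
#' Windowed geometric mean: `out[t] = prod(x[(t - window + 1):t])^(1/window)`
#' for `t >= window`; earlier points are omitted. Any zero in a window yields
#' zero; `NA` in a window (for example a generation where a learner class is
#' empty) yields `NA`.
#'
#' @param x Non-negative numeric series of length `>= window`.
#' @param window Positive integer window, default 3.
#' @return Numeric vector of length `length(x) - window + 1`.
#' @examples
#' geometric_moving_average(c(1, 4, 2), window = 3) # cube root of 8
#' @export
geometric_moving_average <- function(x, window = 3) {
  stopifnot(window >= 1, length(x) >= window)
  if (any(x < 0, na.rm = TRUE)) stop("series must be non-negative")
  n <- length(x)
  vapply(
    seq.int(window, n),
    function(t) prod(x[(t - window + 1L):t])^(1 / window),
    numeric(1)
  )
}
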