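#' Configure one evolutionary trial
#'
#' @param N Population size, `>= 2`.
#' @param env An [env_config()].
#' @param cognition A [cognition_config()]; `N_T` must not exceed `N`.
#' @param max_generations Generation cap; a trial that has not fixated by then
#'   is recorded as censored. Default 10000.
#' @param seed Optional integer seed applied at the start of [run_trial()];
#'   `NULL` leaves the current RNG stream untouched (used by the ensemble
#'   driver, which manages seeding itself).
#' @param record_timeseries Logical; if `TRUE` the trial records
#'   per-generation payoff and prevalence series (off by default to save
#'   memory in sweeps).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(N = 100, env = env_config(B = 10),
                       cognition = cognition_config(),
                       max_generations = 10000, seed = NULL,
                       record_timeseries = FALSE) {
  stopifnot(inherits(env, "env_config"), inherits(cognition, "cognition_config"))
  N <- as.integer(N)
  max_generations <- as.integer(max_generations)
  if (is.na(N) || N < 2) stop("`N` must be an integer >= 2")
  if (cognition$N_T > N) {
    stop("`N_T` cannot exceed `N`: teachers are sampled without replacement")
  }
  if (is.na(max_generations) || max_generations < 1) {
    stop("`max_generations` must be a positive integer")
  }
  structure(
    list(
      N = N, env = env, cognition = cognition,
      max_generations = max_generations, seed = seed,
      record_timeseries = isTRUE(record_timeseries)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> N = %d, B = %d, pi_high = %g, pi_low = %g, u = %g, L = %d, beta = %g, N_T = %d\n",
    x$N, x$env$B, x$env$pi_high, x$env$pi_low, x$env$u, x$env$L,
    x$cognition$beta, x$cognition$N_T
  ))
  invisible(x)
}

#' Create a population of naive agents
#'
#' The population is stored columnar for speed: estimates and counts are
#' `N x B` matrices, traits and net payoffs length-`N` vectors. Row `i` is
#' agent `i`; [population_agent()] extracts a single row as an
#' [init_naive_agent()]-style `agent_state`.
#'
#' @param N Population size.
#' @param B Number of behaviours.
#' @param s Integer vector of length `N` of social-learning traits (0/1).
#' @return An object of class `population`.
#' @export
init_population <- function(N, B, s) {
  stopifnot(length(s) == N, all(s %in% c(0L, 1L)))
  structure(
    list(
      s = as.integer(s),
      est = matrix(0, nrow = N, ncol = B),
      count = matrix(0L, nrow = N, ncol = B),
      net = integer(N)
    ),
    class = "population"
  )
}

#' Extract one agent from a population
#'
#' @param pop A `population`.
#' @param i Agent index.
#' @return An `agent_state` for agent `i`.
#' @export
population_agent <- function(pop, i) {
  structure(
    list(
      s = pop$s[i],
      est_payoff = pop$est[i, ],
      count = pop$count[i, ],
      net_payoff = pop$net[i]
    ),
    class = "agent_state"
  )
}

# Vectorized categorical sampling: one draw per row of a probability matrix.
# Inverse-CDF against a single uniform per row; the last column of the CDF is
# pinned to 1 so floating rounding can never push a draw out of range.
sample_rows <- function(P) {
  n <- nrow(P)
  B <- ncol(P)
  if (B == 1L) return(rep(1L, n))
  cs <- P
  for (j in 2:B) cs[, j] <- cs[, j - 1L] + cs[, j]
  cs[, B] <- 1
  u <- stats::runif(n)
  max.col(u <= cs, ties.method = "first")
}

#' Run one within-generation learning loop
#'
#' Each of the `N` agents performs `L` behaviour choices sequentially and
#' independently: a softmax choice over its current estimates, a Bernoulli
#' payoff draw (`pi_high` on the optimal arm, `pi_low` elsewhere), then the
#' running-mean estimate update. The environment never changes within a
#' generation. Because agents do not interact inside a generation, the loop
#' is vectorized across agents, one synchronous time step at a time; each
#' agent still experiences exactly `L` choose-payoff-update cycles under the
#' per-agent law.
#'
#' @param pop A `population` with all net payoffs zero.
#' @param env An `env_state`.
#' @param cfg A [sim_config()].
#' @return The population with payoffs and beliefs accumulated.
#' @export
run_generation <- function(pop, env, cfg) {
  N <- length(pop$s)
  B <- cfg$env$B
  beta <- cfg$cognition$beta
  opt <- env$optimal_behaviour
  pi_high <- cfg$env$pi_high
  pi_low <- cfg$env$pi_low
  est <- pop$est
  cnt <- pop$count
  net <- pop$net
  rows <- seq_len(N)
  for (t in seq_len(cfg$env$L)) {
    P <- softmax_probabilities(est, beta)
    b <- sample_rows(P)
    p <- ifelse(b == opt, pi_high, pi_low)
    pay <- stats::rbinom(N, 1L, p)
    idx <- cbind(rows, b)
    cnt[idx] <- cnt[idx] + 1L
    est[idx] <- est[idx] + (pay - est[idx]) / cnt[idx]
    net <- net + pay
  }
  pop$est <- est
  pop$count <- cnt
  pop$net <- as.integer(net)
  pop
}

#' Fitness-proportional selection of reproducers
#'
#' Draws `N` parent indices with replacement, each draw picking agent `i`
#' with probability `net_payoff[i] / sum(net_payoff)`. When every net payoff
#' is zero (possible with `pi_low = 0` and small `L`) proportional selection
#' is undefined and the draw falls back to uniform.
#'
#' @param net_payoff Numeric vector of lifetime net payoffs.
#' @param n Number of draws (defaults to the population size).
#' @return Integer vector of `n` parent indices.
#' @export
select_reproducers <- function(net_payoff, n = length(net_payoff)) {
  if (length(net_payoff) == 0) stop("empty population")
  if (sum(net_payoff) == 0) {
    sample.int(length(net_payoff), n, replace = TRUE)
  } else {
    sample.int(length(net_payoff), n, replace = TRUE, prob = net_payoff)
  }
}

#' Payoff-biased teacher choice
#'
#' Samples `N_T` prospective teachers uniformly without replacement from the
#' parent generation (possibly including the child's own parent) and returns
#' the one with the greatest net payoff, ties broken uniformly at random.
#'
#' @param net_payoff Parent generation's net payoffs.
#' @param N_T Prospective-teacher sample size, `<= length(net_payoff)`.
#' @return The chosen teacher's index.
#' @export
select_teacher <- function(net_payoff, N_T) {
  N <- length(net_payoff)
  if (N_T > N) stop("`N_T` cannot exceed the population size")
  cand <- if (N_T == N) seq_len(N) else sample.int(N, N_T)
  pay <- net_payoff[cand]
  best <- which(pay == max(pay))
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  cand[best]
}

#' Exact teacher-choice distribution induced by best-of-N_T sampling
#'
#' [select_teacher()] samples `N_T` candidates uniformly without replacement
#' and returns the best-paying one, ties uniform. Because every child applies
#' this rule independently to the same parent generation, the teacher each
#' child ends up with is an i.i.d. draw from a fixed categorical
#' distribution, which has a closed form: for a parent with net payoff `v`,
#' let `a` be the number of parents paying strictly more and `t` the number
#' paying exactly `v` (including the parent itself). The parent is chosen
#' with probability
#' `(choose(N - a, N_T) - choose(N - a - t, N_T)) / (t * choose(N, N_T))`
#' — the chance the sample contains none of the `a` better parents but at
#' least one of the `t` tied ones, split evenly over the tie class by
#' exchangeability. The population engine draws all teachers in one
#' vectorized call from this distribution; tests check it against the
#' sampling rule empirically.
#'
#' @inheritParams select_teacher
#' @return Numeric vector of selection probabilities summing to 1.
#' @export
teacher_distribution <- function(net_payoff, N_T) {
  N <- length(net_payoff)
  if (N_T > N) stop("`N_T` cannot exceed the population size")
  a <- vapply(net_payoff, function(v) sum(net_payoff > v), numeric(1))
  t <- vapply(net_payoff, function(v) sum(net_payoff == v), numeric(1))
  denom <- lchoose(N, N_T)
  p_win <- exp(lchoose(N - a, N_T) - denom) -
    exp(lchoose(N - a - t, N_T) - denom)
  p_win / t
}

#' One intergenerational step: reproduce, transmit, die off, change
#'
#' Event order is exactly: (1) `N` reproducers are drawn by
#' [select_reproducers()]; (2) each child inherits its parent's
#' social-learning trait without mutation; social-learner children inherit
#' beliefs from a teacher chosen from the parent generation by the
#' best-of-`N_T` payoff-biased rule of [select_teacher()] (drawn i.i.d. per
#' child from its exact distribution, [teacher_distribution()]; teachers may
#' serve many children), asocial children are naive;
#' (3) the parent generation dies off; (4) the environment change process
#' [maybe_change_optimal()] is applied.
#'
#' @param pop The parent `population`, its generation complete.
#' @param env The current `env_state`.
#' @param cfg A [sim_config()].
#' @return A list with elements `pop` (the child generation, payoffs zeroed)
#'   and `env` (possibly changed).
#' @export
step_intergenerational <- function(pop, env, cfg) {
  N <- length(pop$s)
  B <- cfg$env$B
  parents <- select_reproducers(pop$net, N)
  child <- init_population(N, B, pop$s[parents])
  social <- which(child$s == 1L)
  if (length(social) > 0) {
    p_teacher <- teacher_distribution(pop$net, cfg$cognition$N_T)
    teachers <- sample.int(N, length(social), replace = TRUE, prob = p_teacher)
    child$est[social, ] <- pop$est[teachers, , drop = FALSE]
    child$count[social, ] <- (pop$count[teachers, , drop = FALSE] >= 1L) * 1L
  }
  env <- maybe_change_optimal(env, cfg$env)
  list(pop = child, env = env)
}

#' Check for fixation of the social-learning trait
#'
#' @param s Integer vector of social-learning traits.
#' @return `"social_fixation"` if every agent is a social learner,
#'   `"asocial_fixation"` if none is, `"none"` otherwise.
#' @export
check_fixation <- function(s) {
  k <- sum(s)
  if (k == length(s)) "social_fixation"
  else if (k == 0L) "asocial_fixation"
  else "none"
}

#' Run one evolutionary trial to fixation
#'
#' Initializes the environment and a population whose agents carry the
#' social-learning trait independently with probability 1/2 (so about half
#' the initial population learns socially), then alternates within-generation
#' learning and intergenerational steps until the trait fixes. Fixation is
#' checked on each child generation immediately after
#' reproduction/transmission, before those children live; the generation
#' count is the number of completed (lived) generations. A trial that
#' reaches `max_generations` without fixation is censored.
#'
#' @param cfg A [sim_config()]. If `cfg$seed` is non-`NULL` the RNG is seeded
#'   with it first, making the trial a pure function of its configuration.
#' @return An object of class `trial_result`: a list with `outcome` (one of
#'   `"social_fixation"`, `"asocial_fixation"`, `"censored"`), `generations`,
#'   `mean_normalized_payoff` (final lived generation's mean of
#'   `net_payoff / L`; `NA` if the trait was already fixed at
#'   initialization), and, when `cfg$record_timeseries` is `TRUE`,
#'   `timeseries`: a tibble with one row per lived generation giving the mean
#'   normalized payoff overall and per learner class (NA when a class is
#'   empty), the social-learner count, and whether the environment changed at
#'   the start of that generation.
#' @export
run_trial <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  N <- cfg$N
  L <- cfg$env$L
  env <- init_environment(cfg$env)
  pop <- init_population(N, cfg$env$B, s = stats::rbinom(N, 1L, 0.5))
  ts_rows <- if (cfg$record_timeseries) vector("list", 64L) else NULL

  outcome <- check_fixation(pop$s)
  gen <- 0L
  mean_norm <- NA_real_
  while (outcome == "none") {
    pop <- run_generation(pop, env, cfg)
    gen <- gen + 1L
    mean_norm <- mean(pop$net) / L
    if (cfg$record_timeseries) {
      soc <- pop$s == 1L
      ts_rows[[gen]] <- tibble::tibble(
        generation = gen,
        mean_payoff = mean_norm,
        mean_payoff_social = if (any(soc)) mean(pop$net[soc]) / L else NA_real_,
        mean_payoff_asocial = if (any(!soc)) mean(pop$net[!soc]) / L else NA_real_,
        n_social = sum(soc),
        env_changed = env$changed_this_generation
      )
    }
    stepped <- step_intergenerational(pop, env, cfg)
    outcome <- check_fixation(stepped$pop$s)
    if (outcome == "none" && gen >= cfg$max_generations) {
      outcome <- "censored"
      break
    }
    pop <- stepped$pop
    env <- stepped$env
  }

  res <- list(
    outcome = outcome,
    generations = gen,
    mean_normalized_payoff = mean_norm
  )
  if (cfg$record_timeseries) {
    res$timeseries <- do.call(rbind, ts_rows[seq_len(gen)])
  }
  structure(res, class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf(
    "<trial_result> %s after %d generation(s); final mean normalized payoff %s\n",
    x$outcome, x$generations,
    ifelse(is.na(x$mean_normalized_payoff), "NA",
           formatC(x$mean_normalized_payoff, digits = 4, format = "f"))
  ))
  invisible(x)
}
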