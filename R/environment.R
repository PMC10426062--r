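#' Configure the bandit environment
#'
#' The world is a `B`-armed Bernoulli bandit. Exactly one arm (the optimal
#' behaviour) pays 1 with probability `pi_high`; every other arm pays 1 with
#' probability `pi_low`. At each generation boundary a new optimal arm is drawn
#' with probability `u`, always excluding the current one. Agents get `L`
#' opportunities per generation to act and learn (the effective lifespan).
#'
#' The gap `pi_high - pi_low` is the payoff ambiguity: the smaller the gap,
#' the harder it is to tell the optimal behaviour from the rest.
#'
#' @param B Integer number of behaviours (arms). `B >= 2` for evolutionary
#'   experiments; `B = 1` is permitted for degenerate-dynamics testing but is
#'   incompatible with `u > 0` (there is no alternative arm to change to).
#' @param pi_high Expected payoff of the optimal behaviour, in `[0, 1]`.
#' @param pi_low Expected payoff of every non-optimal behaviour, in
#'   `[0, pi_high]`.
#' @param u Per-generation probability that the optimal behaviour changes,
#'   in `[0, 1]`.
#' @param L Positive integer, behaviour/learning opportunities per generation.
#' @return An object of class `env_config`.
#' @examples
#' env_config(B = 10, pi_low = 0.1, u = 0.2, L = 1)
#' @export
env_config <- function(B, pi_high = 0.9, pi_low = 0.1, u = 0, L = 1) {
  stopifnot(
    length(B) == 1, length(pi_high) == 1, length(pi_low) == 1,
    length(u) == 1, length(L) == 1
  )
  B <- as.integer(B)
  L <- as.integer(L)
  if (is.na(B) || B < 1) {
    stop("`B` must be a positive integer (>= 2 for evolutionary runs)")
  }
  if (is.na(pi_high) || pi_high < 0 || pi_high > 1) {
    stop("`pi_high` must lie in [0, 1]")
  }
  if (is.na(pi_low) || pi_low < 0 || pi_low > pi_high) {
    stop("`pi_low` must lie in [0, pi_high]")
  }
  if (is.na(u) || u < 0 || u > 1) stop("`u` must lie in [0, 1]")
  if (is.na(L) || L < 1) stop("`L` must be a positive integer")
  if (B == 1 && u > 0) {
    stop("`u` > 0 requires B >= 2: a changed optimal arm must differ from the current one")
  }
  structure(
    list(B = B, pi_high = pi_high, pi_low = pi_low, u = u, L = L),
    class = "env_config"
  )
}

#' @export
print.env_config <- function(x, ...) {
  cat(sprintf(
    "<env_config> B = %d arms, pi_high = %g, pi_low = %g (ambiguity %g), u = %g, L = %d\n",
    x$B, x$pi_high, x$pi_low, x$pi_high - x$pi_low, x$u, x$L
  ))
  invisible(x)
}

#' Initialize the environment state
#'
#' Draws the optimal behaviour uniformly at random from the `B` arms. Uses the
#' R random number stream; seed it with [set.seed()] for reproducibility.
#'
#' @param config An [env_config()].
#' @return An object of class `env_state` with fields `optimal_behaviour`
#'   (arm index in `1..B`) and `changed_this_generation` (logical, `FALSE`
#'   at initialization; used to annotate time series).
#' @export
init_environment <- function(config) {
  stopifnot(inherits(config, "env_config"))
  structure(
    list(
      optimal_behaviour = sample.int(config$B, 1L),
      changed_this_generation = FALSE
    ),
    class = "env_state"
  )
}

#' Draw a Bernoulli payoff for one behaviour
#'
#' Pays 1 with probability `pi_high` if `b` is the current optimal behaviour,
#' and with probability `pi_low` otherwise. Vectorized over `b`.
#'
#' @param env An `env_state`.
#' @param config The matching [env_config()].
#' @param b Arm index (or vector of indices) in `1..B`.
#' @return Integer payoff(s) in `{0, 1}`, one per element of `b`.
#' @export
draw_payoff <- function(env, config, b) {
  if (any(b < 1L | b > config$B)) stop("arm index out of range 1..B")
  p <- ifelse(b == env$optimal_behaviour, config$pi_high, config$pi_low)
  stats::rbinom(length(b), 1L, p)
}

#' Possibly redraw the optimal behaviour at a generation boundary
#'
#' With probability `u` the optimal behaviour changes; the new optimal arm is
#' drawn uniformly from the `B - 1` arms other than the current one (the
#' current optimal is always excluded). Called exactly once per generation
#' boundary, after reproduction and die-off.
#'
#' @inheritParams draw_payoff
#' @return The updated `env_state`; `changed_this_generation` records whether
#'   a change occurred on this call.
#' @export
maybe_change_optimal <- function(env, config) {
  if (config$u > 0 && config$B < 2) {
    stop("environmental change requires B >= 2")
  }
  if (config$u > 0 && stats::runif(1) < config$u) {
    alternatives <- setdiff(seq_len(config$B), env$optimal_behaviour)
    # sample() on a length-1 vector would sample 1:x; index explicitly
    env$optimal_behaviour <- alternatives[sample.int(length(alternatives), 1L)]
    env$changed_this_generation <- TRUE
  } else {
    env$changed_this_generation <- FALSE
  }
  env
}
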