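#' Cognition constants shared by all agents
#'
#' @param beta Softmax greediness, `>= 0`. Larger `beta` concentrates choice
#'   on the behaviour with the highest estimated payoff; `beta = 0` is uniform
#'   random choice. Default 10.
#' @param N_T Positive integer, number of prospective teachers a social-learner
#'   child samples before picking the best-paying one. Default 5.
#' @return An object of class `cognition_config`.
#' @export
cognition_config <- function(beta = 10, N_T = 5) {
  stopifnot(length(beta) == 1, length(N_T) == 1)
  N_T <- as.integer(N_T)
  if (is.na(beta) || beta < 0) stop("`beta` must be >= 0")
  if (is.na(N_T) || N_T < 1) stop("`N_T` must be a positive integer")
  structure(list(beta = beta, N_T = N_T), class = "cognition_config")
}

#' Softmax (Boltzmann) choice probabilities
#'
#' Maps payoff estimates to choice probabilities proportional to
#' `exp(beta * estimate)`. Computed with the max-shift trick so the result is
#' shift-invariant and safe from overflow for any finite `beta`.
#'
#' Accepts a vector of one agent's estimates or a matrix with one agent per
#' row (the population engine uses the matrix form).
#'
#' @param est_payoff Numeric vector of length `B`, or an `N x B` matrix.
#' @param beta Softmax greediness, `>= 0`.
#' @return Probabilities of the same shape as `est_payoff`; each agent's
#'   probabilities are strictly positive and sum to 1.
#' @examples
#' softmax_probabilities(c(0.9, 0.1), beta = 10)
#' @export
softmax_probabilities <- function(est_payoff, beta) {
  if (length(est_payoff) == 0) stop("empty estimate vector")
  if (anyNA(est_payoff) || any(!is.finite(est_payoff))) {
    stop("estimates must be finite and non-missing")
  }
  if (beta < 0) stop("`beta` must be >= 0")
  if (is.matrix(est_payoff)) {
    z <- beta * est_payoff
    # a single global shift cancels row-wise in the normalization; per-row
    # shifts are only needed when the spread within the matrix could underflow
    zmax <- max(z)
    if (zmax - min(z) > 500) {
      rowmax <- do.call(pmax, lapply(seq_len(ncol(z)), function(j) z[, j]))
      z <- z - rowmax
    } else {
      z <- z - zmax
    }
    w <- exp(z)
    w / rowSums(w)
  } else {
    z <- beta * est_payoff
    w <- exp(z - max(z))
    w / sum(w)
  }
}

#' Sample one behaviour from a choice distribution
#'
#' @param probs Probability vector over the `B` arms (must sum to 1 within
#'   `1e-9`).
#' @return An arm index in `1..length(probs)`.
#' @export
choose_behaviour <- function(probs) {
  if (abs(sum(probs) - 1) > 1e-9 || any(probs < 0)) {
    stop("`probs` is not a probability distribution")
  }
  sample.int(length(probs), 1L, prob = probs)
}

#' Create a naive agent
#'
#' All payoff estimates and observation counts start at zero, as does the
#' cumulative payoff; a naive agent's softmax choice is uniform.
#'
#' @param B Number of behaviours.
#' @param s Heritable social-learning trait: 1 = social learner, 0 = asocial.
#' @return An object of class `agent_state` with fields `s`, `est_payoff`
#'   (length-`B`), `count` (length-`B`), `net_payoff`.
#' @export
init_naive_agent <- function(B, s = 0L) {
  stopifnot(B >= 1, s %in% c(0L, 1L))
  structure(
    list(
      s = as.integer(s),
      est_payoff = numeric(B),
      count = integer(B),
      net_payoff = 0L
    ),
    class = "agent_state"
  )
}

#' Update an agent's payoff estimate after performing a behaviour
#'
#' The observation count for arm `b` is incremented first; then the estimate
#' is moved toward the observed payoff by a running (moving arithmetic)
#' average step using the post-increment count:
#' `est <- est + (payoff - est) / count`. Starting from a zero count, the
#' estimate after `k` updates is exactly the arithmetic mean of the `k`
#' payoffs. The cumulative payoff is incremented by the payoff.
#'
#' @param agent An `agent_state`.
#' @param b Arm index in `1..B`.
#' @param payoff Observed payoff in `{0, 1}`.
#' @return The updated `agent_state`.
#' @export
update_estimate <- function(agent, b, payoff) {
  stopifnot(b >= 1, b <= length(agent$est_payoff), payoff %in% c(0, 1))
  agent$count[b] <- agent$count[b] + 1L
  agent$est_payoff[b] <- agent$est_payoff[b] +
    (payoff - agent$est_payoff[b]) / agent$count[b]
  agent$net_payoff <- agent$net_payoff + as.integer(payoff)
  agent
}

#' Build a social-learner child from a teacher's beliefs
#'
#' The child copies the teacher's mean-payoff estimates verbatim for every
#' arm. Each observation count is set to 1 if the teacher observed that arm
#' at least once and to 0 otherwise: the child treats the teacher's whole
#' experience of an arm as a single observation, so its own next observation
#' of that arm is averaged in with weight 1/2, keeping social learners
#' flexible when the environment has moved on. The child starts its life with
#' zero cumulative payoff.
#'
#' @param teacher An `agent_state` that has completed its generation.
#' @return A new `agent_state` with `s = 1`.
#' @export
transmit_from_teacher <- function(teacher) {
  structure(
    list(
      s = 1L,
      est_payoff = teacher$est_payoff,
      count = as.integer(teacher$count >= 1L),
      net_payoff = 0L
    ),
    class = "agent_state"
  )
}
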