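# Shared test helpers: binomial confidence machinery and tiny constructors.

# Two-sided binomial acceptance band for an observed count of successes out
# of n at success probability p. The per-assertion level is 99.9% because
# the suite makes dozens of these checks; at 99% each the family-wise
# false-alarm probability would be substantial, while a genuinely biased
# implementation still lands many sigmas out at the sample sizes used.
within_binom_ci <- function(count, n, p) {
  lo <- stats::qbinom(0.0005, n, p)
  hi <- stats::qbinom(0.9995, n, p)
  count >= lo && count <= hi
}

# Pooled standard error of the difference between two proportions.
pooled_se <- function(p1, n1, p2, n2) {
  sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
}

# Quick sim_config builder for tests.
test_cfg <- function(B = 2, pi_high = 0.9, pi_low = 0.1, u = 0, L = 1,
                     N = 100, beta = 10, N_T = 5, max_generations = 10000,
                     seed = NULL, record_timeseries = FALSE) {
  sim_config(
    N = N,
    env = env_config(B = B, pi_high = pi_high, pi_low = pi_low, u = u, L = L),
    cognition = cognition_config(beta = beta, N_T = N_T),
    max_generations = max_generations, seed = seed,
    record_timeseries = record_timeseries
  )
}
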