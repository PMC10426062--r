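#' Specify a parameter sweep
#'
#' Enumerates the full factorial grid of the four uncertainty dimensions:
#' environmental variability `u`, selection-set size `B`, payoff ambiguity
#' (through `pi_low`), and effective lifespan `L`. The remaining parameters
#' are held fixed across the sweep. Defaults bracket the headline study
#' conditions: `pi_high = 0.9`, `beta = 10`, `N_T = 5`, 1000 trials per
#' combination.
#'
#' @param u Grid of environmental-variability values.
#' @param B Grid of selection-set sizes.
#' @param pi_low Grid of non-optimal payoff probabilities.
#' @param L Grid of effective lifespans.
#' @param pi_high Optimal-behaviour payoff probability, fixed.
#' @param N Population size.
#' @param N_T Prospective-teacher sample size.
#' @param beta Softmax greediness.
#' @param n_trials Trials per combination.
#' @param base_seed Master seed for the whole sweep.
#' @param max_generations Per-trial generation cap.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(u = seq(0, 0.9, by = 0.1),
                       B = c(2, 4, 10),
                       pi_low = c(0.1, 0.45, 0.8),
                       L = c(1, 4, 8, 20),
                       pi_high = 0.9, N = 100, N_T = 5, beta = 10,
                       n_trials = 1000, base_seed = 1,
                       max_generations = 10000) {
  stopifnot(n_trials >= 1, length(u) >= 1, length(B) >= 1,
            length(pi_low) >= 1, length(L) >= 1)
  structure(
    list(
      u = as.numeric(u), B = as.integer(B), pi_low = as.numeric(pi_low),
      L = as.integer(L), pi_high = pi_high, N = as.integer(N),
      N_T = as.integer(N_T), beta = beta, n_trials = as.integer(n_trials),
      base_seed = as.integer(base_seed),
      max_generations = as.integer(max_generations)
    ),
    class = "sweep_spec"
  )
}

#' Read a sweep specification from a YAML file
#'
#' The file's keys mirror the arguments of [sweep_spec()]; unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `sweep_spec`.
#' @export
read_sweep_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `N` key as boolean FALSE; map it back
  names(raw)[names(raw) == "FALSE"] <- "N"
  allowed <- names(formals(sweep_spec))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sweep_spec, raw)
}

#' Run a full parameter sweep
#'
#' Runs [run_ensemble()] for every `(u, B, pi_low, L)` combination of the
#' spec, each combination's trials seeded reproducibly from the spec's
#' `base_seed`, so results are independent of evaluation order. Optionally
#' writes the table as CSV plus a JSON run manifest (spec, seed, package
#' version) alongside it.
#'
#' @param spec A [sweep_spec()].
#' @param out_csv Optional path; if given, the result table is written there
#'   and a manifest to `<out_csv>.manifest.json`.
#' @param verbose Print one progress line per combination.
#' @return A tibble with one row per combination: the four swept parameters,
#'   the fixed parameters, and the ensemble aggregates of [run_ensemble()].
#' @export
run_sweep <- function(spec, out_csv = NULL, verbose = interactive()) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- expand.grid(
    u = spec$u, B = spec$B, pi_low = spec$pi_low, L = spec$L,
    KEEP.OUT.ATTRS = FALSE
  )
  combo_seeds <- draw_trial_seeds(spec$base_seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- sim_config(
      N = spec$N,
      env = env_config(B = g$B, pi_high = spec$pi_high, pi_low = g$pi_low,
                       u = g$u, L = g$L),
      cognition = cognition_config(beta = spec$beta, N_T = spec$N_T),
      max_generations = spec$max_generations
    )
    summ <- run_ensemble(cfg, n_trials = spec$n_trials,
                         base_seed = combo_seeds[i])
    rows[[i]] <- tibble::tibble(
      u = g$u, B = g$B, pi_low = g$pi_low, L = g$L,
      pi_high = spec$pi_high, N = spec$N, N_T = spec$N_T, beta = spec$beta,
      summ
    )
    if (verbose) {
      message(sprintf(
        "[%d/%d] u=%.2f B=%d pi_low=%.2f L=%d: rho_hat=%.3f (%d censored)",
        i, nrow(grid), g$u, g$B, g$pi_low, g$L,
        rows[[i]]$rho_hat, rows[[i]]$n_censored
      ))
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out_csv)) {
    utils::write.csv(res, out_csv, row.names = FALSE)
    manifest <- list(
      package = "slbandit",
      version = as.character(utils::packageVersion("slbandit")),
      base_seed = spec$base_seed,
      spec = unclass(spec)
    )
    jsonlite::write_json(manifest, paste0(out_csv, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' Ceiling table for one (B, pi_low, L) slice of a sweep
#'
#' Convenience wrapper: runs an ensemble across an ascending `u` grid at a
#' fixed `(B, pi_low, L)` combination and applies
#' [social_learning_ceiling()].
#'
#' @param u Ascending grid of `u` values.
#' @inheritParams sweep_spec
#' @param B,pi_low,L Single values for this slice.
#' @return A list with `table` (tibble of `u` and ensemble aggregates) and
#'   `u_c` (the ceiling, `NA_real_` when above the grid).
#' @export
ceiling_for_slice <- function(u, B, pi_low, L, pi_high = 0.9, N = 100,
                              N_T = 5, beta = 10, n_trials = 1000,
                              base_seed = 1, max_generations = 10000,
                              verbose = FALSE) {
  spec <- sweep_spec(
    u = u, B = B, pi_low = pi_low, L = L, pi_high = pi_high, N = N,
    N_T = N_T, beta = beta, n_trials = n_trials, base_seed = base_seed,
    max_generations = max_generations
  )
  tab <- run_sweep(spec, verbose = verbose)
  list(
    table = tab,
    u_c = social_learning_ceiling(tab$u, tab$rho_hat)
  )
}
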