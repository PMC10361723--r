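# Synthetic situs-outcome series drawn from the generative symmetry model at
# known stage weights, for parameter-recovery testing of fit_weights().

#' Configuration for the synthetic outcome-series generator
#'
#' @param true_weights A [stage_weights()] used as ground truth.
#' @param scenarios List of [intervention_scenario()] objects.
#' @param n_per_series Embryos per series (>= 1).
#' @param seed Integer root seed.
#' @param int_params,sham_params,fractions AAV model parameters.
#' @return Object of class `outcome_config`.
#' @export
outcome_config <- function(true_weights, scenarios, n_per_series = 500,
                           seed = 1L,
                           int_params = intervention_aav_params(),
                           sham_params = sham_aav_params(),
                           fractions = motile_cilia_fractions()) {
  stopifnot(inherits(true_weights, "stage_weights"), n_per_series >= 1)
  if (!all(vapply(scenarios, inherits, logical(1), "intervention_scenario"))) {
    stop("scenarios must be intervention_scenario objects")
  }
  structure(as.list(environment()), class = "outcome_config")
}

#' Generate situs-outcome series from known stage weights
#'
#' For each scenario, draws per-embryo AAV trajectories, integrates the
#' symmetry-breaking signal, assigns normal situs with probability `p_high`
#' above threshold or `p_base` below, and records the abnormal count.
#'
#' @param config An [outcome_config()].
#' @return List of [outcome_series()], one per scenario.
#' @export
generate_outcome_series <- function(config) {
  stopifnot(inherits(config, "outcome_config"))
  set.seed(config$seed)
  lapply(config$scenarios, function(sc) {
    traj <- sample_trajectories(config$n_per_series, sc, config$int_params,
                                config$sham_params, config$fractions)
    p_norm <- outcome_probability(integrate_signal(traj, config$true_weights),
                                  config$true_weights)
    normal <- rbinom(config$n_per_series, 1, p_norm)
    outcome_series(sc, config$n_per_series, sum(normal == 0))
  })
}
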