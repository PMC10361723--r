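# Probabilistic signal-integration model of symmetry breaking.
#
# A virtual embryo integrates its anterior angular velocity over somite
# stages 3-8 with unknown stage sensitivities W(t):
#   S = sum_t AAV(t) * W(t).
# The embryo develops normal situs with probability 0.9 if S exceeds the
# threshold (1, arbitrary units) and 0.5 otherwise. Stage weights are fitted
# by maximizing a binomial log-likelihood over observed intervention outcome
# series, with the defect probability of each series computed from simulated
# virtual embryos under that scenario.

#' Stage sensitivity weights
#'
#' @param w Named (or length-6) non-negative vector of weights for stages
#'   3-8, in arbitrary units relative to the threshold.
#' @param threshold Signal threshold (default 1).
#' @param p_base Probability of normal situs below threshold (default 0.5).
#' @param p_high Probability of normal situs above threshold (default 0.9).
#' @return Object of class `stage_weights`.
#' @export
stage_weights <- function(w = rep(1, 6), threshold = 1, p_base = 0.5,
                          p_high = 0.9) {
  if (length(w) != 6) stop("weights must cover stages 3..8")
  if (any(w < 0)) stop("weights must be non-negative")
  if (p_base < 0 || p_high > 1 || p_base > p_high) {
    stop("need 0 <= p_base <= p_high <= 1")
  }
  w <- as.numeric(w)
  names(w) <- as.character(3:8)
  structure(list(w = w, threshold = threshold, p_base = p_base,
                 p_high = p_high), class = "stage_weights")
}

#' Integrated symmetry-breaking signal
#'
#' `S = sum_t AAV(t) * W(t)` over stages 3-8.
#'
#' @param trajectory Numeric length-6 vector (stages 3-8) or an `n x 6`
#'   matrix of trajectories.
#' @param weights A [stage_weights()].
#' @return Scalar or vector of signals.
#' @export
integrate_signal <- function(trajectory, weights) {
  stopifnot(inherits(weights, "stage_weights"))
  if (is.matrix(trajectory)) {
    if (ncol(trajectory) != 6) stop("trajectories must have 6 stage columns")
    drop(trajectory %*% weights$w)
  } else {
    if (length(trajectory) != 6) stop("trajectory must cover stages 3..8")
    sum(trajectory * weights$w)
  }
}

#' Probability of normal situs given the integrated signal
#'
#' `p_high` if the signal strictly exceeds the threshold, `p_base` otherwise
#' (a signal exactly at threshold counts as not exceeded).
#'
#' @param S Signal value(s).
#' @param weights A [stage_weights()] (carries threshold and rates).
#' @return Probability vector.
#' @export
outcome_probability <- function(S, weights) {
  stopifnot(all(is.finite(S)))
  ifelse(S > weights$threshold, weights$p_high, weights$p_base)
}

#' One observed intervention outcome series
#'
#' @param scenario An [intervention_scenario()].
#' @param n Number of embryos in the series.
#' @param n_abnormal Number with abnormal situs (or abnormal marker
#'   expression), `0 <= n_abnormal <= n`.
#' @return Object of class `outcome_series`.
#' @export
outcome_series <- function(scenario, n, n_abnormal) {
  stopifnot(inherits(scenario, "intervention_scenario"))
  if (n_abnormal < 0 || n_abnormal > n) stop("need 0 <= n_abnormal <= n")
  structure(list(scenario = scenario, n = as.integer(n),
                 n_abnormal = as.integer(n_abnormal)),
            class = "outcome_series")
}

#' Fluid-extraction outcome series
#'
#' The default experiment series fitted by [fit_weights()]: laterality
#' outcome counts after fluid extraction at single stages 3-6 ss, the double
#' intervention at 5 + 7 ss, and an unmanipulated control series.
#'
#' @return List of [outcome_series()] objects.
#' @export
extraction_outcome_series <- function() {
  list(
    outcome_series(intervention_scenario("sham"), 26, 0),
    outcome_series(intervention_scenario("3ss", 3), 13, 2),
    outcome_series(intervention_scenario("4ss", 4), 26, 7),
    outcome_series(intervention_scenario("5ss", 5), 40, 14),
    outcome_series(intervention_scenario("6ss", 6), 27, 4),
    outcome_series(intervention_scenario("5+7ss", c(5, 7)), 16, 6))
}

#' Predicted defect probability of a scenario
#'
#' Simulates `n_virtual` virtual embryos under the scenario, integrates their
#' signals and returns the predicted probability of abnormal situs. By
#' default the exact mean of `1 - outcome_probability(S)` over embryos is
#' returned (same estimand as literal per-embryo Bernoulli draws, lower
#' variance); `bernoulli = TRUE` restores literal draws.
#'
#' @param weights A [stage_weights()].
#' @param scenario An [intervention_scenario()], or a precomputed trajectory
#'   matrix from [sample_trajectories()].
#' @param n_virtual Virtual embryos per evaluation (default 1000).
#' @param int_params,sham_params,fractions AAV model parameters.
#' @param seed Optional seed for the trajectory draws.
#' @param bernoulli If `TRUE`, draw one Bernoulli outcome per virtual embryo.
#' @return Predicted defect probability (scalar in `[1 - p_high, 1 - p_base]`).
#' @export
simulate_series <- function(weights, scenario, n_virtual = 1000,
                            int_params = intervention_aav_params(),
                            sham_params = sham_aav_params(),
                            fractions = motile_cilia_fractions(),
                            seed = NULL, bernoulli = FALSE) {
  traj <- if (is.matrix(scenario)) scenario else {
    sample_trajectories(n_virtual, scenario, int_params, sham_params,
                        fractions, seed = seed)
  }
  p_normal <- outcome_probability(integrate_signal(traj, weights), weights)
  if (bernoulli) {
    mean(rbinom(length(p_normal), 1, p_normal) == 0)
  } else {
    mean(1 - p_normal)
  }
}

# Precompute one trajectory matrix per series under common random numbers so
# the likelihood is deterministic in (weights, seed) across optimizer calls.
.series_trajectories <- function(series, n_virtual, int_params, sham_params,
                                 fractions, seed) {
  set.seed(seed)
  lapply(series, function(s) {
    sample_trajectories(n_virtual, s$scenario, int_params, sham_params,
                        fractions)
  })
}

.series_ll <- function(w_vec, series, trajs, threshold, p_base, p_high) {
  ll <- 0
  for (i in seq_along(series)) {
    S <- drop(trajs[[i]] %*% w_vec)
    p_def <- mean(ifelse(S > threshold, 1 - p_high, 1 - p_base))
    p_def <- min(max(p_def, 1e-6), 1 - 1e-6)
    ll <- ll + dbinom(series[[i]]$n_abnormal, series[[i]]$n, p_def, log = TRUE)
  }
  ll
}

#' Binomial log-likelihood of stage weights
#'
#' Each series' observed abnormal count is modelled as binomial with the
#' defect probability predicted by [simulate_series()] (clipped to
#' `[1e-6, 1 - 1e-6]`). Trajectories are drawn once per seed and reused
#' across weight evaluations (common random numbers), so the value is
#' deterministic given `(weights, seed)`.
#'
#' @param weights A [stage_weights()].
#' @param series List of [outcome_series()].
#' @param n_virtual Virtual embryos per series.
#' @param int_params,sham_params,fractions AAV model parameters.
#' @param seed Seed for the common trajectory draws.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(weights, series, n_virtual = 1000,
                           int_params = intervention_aav_params(),
                           sham_params = sham_aav_params(),
                           fractions = motile_cilia_fractions(), seed = 1L) {
  if (length(series) == 0) stop("series must be non-empty")
  trajs <- .series_trajectories(series, n_virtual, int_params, sham_params,
                                fractions, seed)
  .series_ll(weights$w, series, trajs, weights$threshold, weights$p_base,
             weights$p_high)
}

#' Fit stage weights by multistart maximum likelihood
#'
#' Maximizes the binomial log-likelihood over the weight box
#' `[bounds[1], bounds[2]]^6` by bounded local optimization (`L-BFGS-B`) from
#' the uniform initial guess `W = 1` plus `n_starts - 1` random starts in the
#' box; the best incumbent over all starts is returned. Restricted stages are
#' pinned at exactly 0. Trajectories are drawn once (common random numbers)
#' so the objective is smooth in the weights between threshold crossings.
#'
#' @param series List of [outcome_series()] (default
#'   [extraction_outcome_series()]).
#' @param restriction Integer stages (subset of 3-8) whose weights are forced
#'   to 0.
#' @param n_starts Number of multistart local optimizations (default 200).
#' @param bounds Length-2 box bounds per weight (default `c(0, 5)`).
#' @param n_virtual Virtual embryos per series per likelihood evaluation.
#' @param int_params,sham_params,fractions AAV model parameters.
#' @param seed Seed controlling both the common trajectory draws and the
#'   random start locations.
#' @param weights_template A [stage_weights()] carrying threshold and rates.
#' @return Object of class `weight_fit`: `weights` (fitted [stage_weights()]),
#'   `log_likelihood`, `predicted` (per-series defect probabilities, named by
#'   scenario label), `observed` (observed defect fractions), `contributions`
#'   (normalized per-stage signal contributions), `restriction`, and `starts`
#'   (data frame of each start's final objective value).
#' @export
fit_weights <- function(series = extraction_outcome_series(),
                        restriction = integer(), n_starts = 200,
                        bounds = c(0, 5), n_virtual = 1000,
                        int_params = intervention_aav_params(),
                        sham_params = sham_aav_params(),
                        fractions = motile_cilia_fractions(), seed = 1L,
                        weights_template = stage_weights()) {
  stopifnot(all(restriction %in% 3:8), length(bounds) == 2,
            all(is.finite(bounds)))
  trajs <- .series_trajectories(series, n_virtual, int_params, sham_params,
                                fractions, seed)
  free <- setdiff(3:8, restriction)
  free_idx <- match(free, 3:8)
  thr <- weights_template$threshold
  pb <- weights_template$p_base
  ph <- weights_template$p_high
  objective <- function(wf) {
    w <- numeric(6)
    w[free_idx] <- wf
    -.series_ll(w, series, trajs, thr, pb, ph)
  }
  d <- length(free_idx)
  starts <- rbind(rep(1, d),
                  matrix(runif((n_starts - 1) * d, bounds[1], bounds[2]),
                         ncol = d))
  # The simulated defect probabilities move in steps of 1 / n_virtual, so the
  # objective is a staircase; a finite-difference step wide enough to span
  # several staircase treads is needed for the bounded quasi-Newton solver.
  ctrl <- list(ndeps = rep(0.01, d))
  run_local <- function(par) {
    tryCatch(optim(par, objective, method = "L-BFGS-B",
                   lower = rep(bounds[1], d), upper = rep(bounds[2], d),
                   control = ctrl),
             error = function(e) NULL)
  }
  best <- NULL
  final_vals <- numeric(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    res <- run_local(starts[i, ])
    if (is.null(res)) {
      final_vals[i] <- NA_real_
      next
    }
    final_vals[i] <- -res$value
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all ", nrow(starts), " optimization starts failed")
  # polish the incumbent with a coarser and a finer difference step
  for (nd in c(0.05, 0.002)) {
    ctrl <- list(ndeps = rep(nd, d))
    res <- run_local(best$par)
    if (!is.null(res) && res$value < best$value) best <- res
  }
  w <- numeric(6)
  w[free_idx] <- best$par
  fitted <- stage_weights(w, threshold = thr, p_base = pb, p_high = ph)
  predicted <- vapply(seq_along(series), function(i) {
    simulate_series(fitted, trajs[[i]])
  }, numeric(1))
  names(predicted) <- vapply(series, function(s) s$scenario$label, character(1))
  observed <- vapply(series, function(s) s$n_abnormal / s$n, numeric(1))
  names(observed) <- names(predicted)
  structure(list(weights = fitted,
                 log_likelihood = -best$value,
                 predicted = predicted, observed = observed,
                 contributions = stage_contributions(fitted, sham_params,
                                                     fractions),
                 restriction = sort(as.integer(restriction)),
                 starts = data.frame(start = seq_len(nrow(starts)),
                                     log_likelihood = final_vals)),
            class = "weight_fit")
}

#' Normalized per-stage signal contributions
#'
#' Contribution of stage `t` is its sensitivity multiplied by the expected
#' unperturbed flow strength, `W(t) * E[AAV_sham(t)]`, normalized to sum to
#' one. If all weights are zero the contributions are reported as zeros with
#' attribute `all_zero = TRUE`.
#'
#' @param weights A [stage_weights()].
#' @param sham_params,fractions Sham AAV model parameters.
#' @return Named numeric vector over stages 3-8.
#' @export
stage_contributions <- function(weights, sham_params = sham_aav_params(),
                                fractions = motile_cilia_fractions()) {
  flow <- mean_trajectory(intervention_scenario("sham"),
                          sham_params = sham_params, fractions = fractions)
  raw <- weights$w * flow
  if (all(raw == 0)) {
    return(structure(setNames(numeric(6), as.character(3:8)),
                     all_zero = TRUE))
  }
  raw / sum(raw)
}

#' @export
print.weight_fit <- function(x, ...) {
  cat("Stage-weight fit (log-likelihood ", format(x$log_likelihood, digits = 6),
      ")\n", sep = "")
  if (length(x$restriction)) {
    cat("  restricted (W = 0):", paste(x$restriction, "ss"), "\n")
  }
  cat("  weights:\n")
  print(round(x$weights$w, 4))
  cat("  contributions:\n")
  print(round(x$contributions, 4))
  cat("  predicted vs observed defect rates:\n")
  print(round(rbind(predicted = x$predicted, observed = x$observed), 3))
  invisible(x)
}
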