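# Statistical models of anterior angular velocity (AAV) over somite stages
# 3-8 under sham and fluid-extraction scenarios.
#
# The recovery curve after extraction at stage 5 is
#   AAV(t) = phi1 * [sigma(k_r (t - 5 - phi2)) - sigma(-k_r phi2)]
#            + phi3 * sigma(k_l (t - 5.5))
# with logistic sigma, k_r = 0.9 and k_l = 8 chosen so the curve rises
# smoothly from (approximately) zero at the intervention stage. Only phi3
# carries a between-embryo random effect. The sham curve is linear,
# AAV(t) = phi1_s + phi2_s (t - 5), with a random intercept. AAV below 6 ss
# is rescaled by the motile-cilia fraction at each stage relative to 6 ss,
# reflecting that flow strength scales with the fraction of cilia that have
# become motile (linearity of Stokes flow).

#' Fixed and random effects of the post-extraction AAV recovery curve
#'
#' @param phi1,phi2,phi3 Fixed effects (rad/s, stages, rad/s).
#' @param sd_phi3 Between-embryo SD of `phi3`.
#' @param k_recovery,k_late Sigmoid steepness constants (fixed by design, not
#'   fitted).
#' @param t_ref Stage the curve is anchored at (intervention stage).
#' @param t_late Center of the late sigmoid term.
#' @return Object of class `intervention_aav_params`.
#' @export
intervention_aav_params <- function(phi1 = 0.778, phi2 = 0.969, phi3 = 0.126,
                                    sd_phi3 = 0.169, k_recovery = 0.9,
                                    k_late = 8, t_ref = 5, t_late = 5.5) {
  if (k_recovery <= 0 || k_late <= 0) stop("sigmoid steepness must be positive")
  if (sd_phi3 < 0) stop("sd_phi3 must be non-negative")
  structure(as.list(environment()), class = "intervention_aav_params")
}

#' Fixed and random effects of the sham AAV model
#'
#' @param phi1_s Intercept at 5 ss (rad/s).
#' @param phi2_s Slope per somite stage (rad/s/stage).
#' @param sd_phi1_s Between-embryo SD of the intercept.
#' @return Object of class `sham_aav_params`.
#' @export
sham_aav_params <- function(phi1_s = 0.356, phi2_s = 0.0362,
                            sd_phi1_s = 0.0378) {
  if (sd_phi1_s < 0) stop("sd_phi1_s must be non-negative")
  structure(as.list(environment()), class = "sham_aav_params")
}

#' Motile cilia fractions by somite stage
#'
#' Percentage of LRO cilia that are motile at stages 3-6; flow at early
#' stages is rescaled by these fractions relative to 6 ss.
#'
#' @param percent Named numeric, stage -> percent motile.
#' @return Object of class `motile_cilia_fractions`.
#' @export
motile_cilia_fractions <- function(percent = c(`3` = 5.57, `4` = 42.9,
                                               `5` = 62.1, `6` = 76.3)) {
  if (any(diff(percent) <= 0)) stop("fractions must be strictly increasing in stage")
  if (any(percent <= 0 | percent > 100)) stop("fractions must lie in (0, 100]")
  structure(list(percent = percent), class = "motile_cilia_fractions")
}

#' Mean AAV of the post-extraction recovery curve
#'
#' Evaluates the fitted nonlinear recovery curve at stage `t` with a given
#' draw of the random-effect parameter `phi3`. At `t = t_ref` the value is
#' approximately zero (the flow has just been removed).
#'
#' @param t Somite stage (real-valued, `>= t_ref`).
#' @param params An [intervention_aav_params()].
#' @param phi3_draw Value of the third parameter for this embryo (defaults to
#'   the fixed effect).
#' @return AAV in rad/s.
#' @export
intervention_mean <- function(t, params = intervention_aav_params(),
                              phi3_draw = params$phi3) {
  if (any(t < params$t_ref)) stop("t must be >= t_ref")
  params$phi1 * (plogis(params$k_recovery * (t - params$t_ref - params$phi2)) -
                   plogis(-params$k_recovery * params$phi2)) +
    phi3_draw * plogis(params$k_late * (t - params$t_late))
}

#' Mean AAV under sham intervention
#'
#' @param t Somite stage.
#' @param params A [sham_aav_params()].
#' @param phi1_draw Embryo-level intercept draw (defaults to the fixed effect).
#' @return AAV in rad/s.
#' @export
sham_mean <- function(t, params = sham_aav_params(),
                      phi1_draw = params$phi1_s) {
  phi1_draw + params$phi2_s * (t - 5)
}

#' Rescale AAV at early stages by motile-cilia fraction
#'
#' `AAV(t) = fraction(t) / fraction(6) * aav6` for `t` in 3-5, e.g.
#' `AAV(3) = 5.57 / 76.3 * AAV(6)`.
#'
#' @param aav6 AAV at 6 ss (rad/s).
#' @param t Stage, one of 3, 4, 5 (vectorized).
#' @param fractions A [motile_cilia_fractions()].
#' @return Rescaled AAV (rad/s).
#' @export
rescale_early <- function(aav6, t, fractions = motile_cilia_fractions()) {
  if (!all(t %in% 3:5)) stop("t must be in {3, 4, 5}")
  p <- fractions$percent
  unname(p[as.character(t)] / p["6"] * aav6)
}

#' Intervention scenario
#'
#' @param label Scenario label.
#' @param extraction_stages Sorted somite stages at which fluid was extracted
#'   (subset of 3-12; empty for sham).
#' @return Object of class `intervention_scenario`.
#' @export
intervention_scenario <- function(label, extraction_stages = integer()) {
  s <- as.integer(extraction_stages)
  if (anyDuplicated(s) || is.unsorted(s)) stop("extraction stages must be sorted and unique")
  if (length(s) && (min(s) < 3 || max(s) > 12)) stop("extraction stages must lie in 3..12")
  structure(list(label = label, extraction_stages = s),
            class = "intervention_scenario")
}

# Deterministic AAV(3..8) for one embryo given its random-effect draws.
# Composition: sham values before the first extraction (with motile-cilia
# rescaling below 6 ss); after each extraction the recovery curve re-anchored
# at the extraction stage; for extractions before 5 ss the shifted curve is
# itself damped by the motile-cilia fraction at stages 3-5 (few cilia are
# motile yet, so the recovering flow is proportionally weaker).
.trajectory_one <- function(scenario, phi1s_draw, phi3_draw,
                            int_params, sham_params, fractions) {
  stages <- 3:8
  frac <- fractions$percent
  damp <- function(t) ifelse(t <= 5, frac[as.character(pmax(t, 3))] / frac["6"], 1)
  aav6_sham <- sham_mean(6, sham_params, phi1s_draw)
  sham_val <- function(t) {
    ifelse(t <= 5, unname(frac[as.character(t)] / frac["6"]) * aav6_sham,
           sham_mean(t, sham_params, phi1s_draw))
  }
  ext <- scenario$extraction_stages
  ext <- ext[ext <= 8]  # later extractions do not affect the 3..8 window
  vals <- sham_val(stages)
  for (k in seq_along(ext)) {
    s <- ext[k]
    upto <- if (k < length(ext)) ext[k + 1] - 1 else 8
    idx <- stages >= s & stages <= upto
    t_eval <- stages[idx]
    # re-anchor the fitted 5 ss recovery curve at the extraction stage
    shifted <- intervention_mean(t_eval - (s - int_params$t_ref), int_params,
                                 phi3_draw)
    vals[idx] <- shifted * unname(damp(t_eval))
  }
  unname(vals)
}

#' Sample one per-embryo AAV trajectory
#'
#' Draws the embryo-level random effects (`phi1` of the sham model, `phi3` of
#' the recovery curve) and composes the stage 3-8 AAV trajectory for the
#' scenario: sham flow before the first extraction, the re-anchored recovery
#' curve after each extraction (restarting at the second extraction for
#' double interventions), with motile-cilia rescaling at stages 3-5.
#'
#' @param scenario An [intervention_scenario()].
#' @param int_params,sham_params,fractions Model parameter objects.
#' @param seed Optional integer seed.
#' @return Numeric vector of length 6 named by stage (3-8), rad/s.
#' @export
sample_trajectory <- function(scenario,
                              int_params = intervention_aav_params(),
                              sham_params = sham_aav_params(),
                              fractions = motile_cilia_fractions(),
                              seed = NULL) {
  drop(sample_trajectories(1, scenario, int_params, sham_params, fractions,
                           seed = seed))
}

#' Sample many per-embryo AAV trajectories
#'
#' @param n Number of virtual embryos.
#' @inheritParams sample_trajectory
#' @return An `n x 6` matrix, columns named by stage 3-8.
#' @export
sample_trajectories <- function(n, scenario,
                                int_params = intervention_aav_params(),
                                sham_params = sham_aav_params(),
                                fractions = motile_cilia_fractions(),
                                seed = NULL) {
  stopifnot(inherits(scenario, "intervention_scenario"))
  if (!is.null(seed)) set.seed(seed)
  phi1s <- rnorm(n, sham_params$phi1_s, sham_params$sd_phi1_s)
  phi3 <- rnorm(n, int_params$phi3, int_params$sd_phi3)
  out <- t(vapply(seq_len(n), function(i) {
    .trajectory_one(scenario, phi1s[i], phi3[i], int_params, sham_params,
                    fractions)
  }, numeric(6)))
  colnames(out) <- as.character(3:8)
  out
}

#' Population-mean AAV trajectory
#'
#' The trajectory evaluated at the fixed effects (random-effect SDs ignored);
#' because the random effects enter linearly this equals the expected
#' trajectory.
#'
#' @inheritParams sample_trajectory
#' @return Numeric vector of length 6 named by stage.
#' @export
mean_trajectory <- function(scenario,
                            int_params = intervention_aav_params(),
                            sham_params = sham_aav_params(),
                            fractions = motile_cilia_fractions()) {
  v <- .trajectory_one(scenario, sham_params$phi1_s, int_params$phi3,
                       int_params, sham_params, fractions)
  names(v) <- as.character(3:8)
  v
}

#' Fit the AAV stage models to per-embryo observations
#'
#' Nonlinear (intervention) or linear (sham) mixed-effects estimation of the
#' AAV curve parameters, with a single embryo-level random effect (`phi3` for
#' the recovery curve, the intercept for the sham model). The nonlinear fit
#' uses multiple starting points and returns the best converged fit.
#'
#' @param observations Data frame with `embryo_id`, `stage`, `aav`.
#' @param model `"sham"` or `"intervention"`.
#' @param starts For the intervention model, a matrix or data frame of
#'   starting values with columns `phi1`, `phi2`, `phi3` (defaults to a small
#'   grid around plausible values).
#' @return List with `model`, `params` (the corresponding parameter object
#'   with fitted values), `se` (fixed-effect standard errors), `logLik` and
#'   `fit` (the underlying fit object).
#' @export
fit_aav_model <- function(observations, model = c("sham", "intervention"),
                          starts = NULL) {
  model <- match.arg(model)
  obs <- observations
  if (length(unique(obs$embryo_id)) < 5) stop("need at least 5 embryos")
  if (length(unique(obs$stage)) < 2) stop("need at least 2 stages (unidentifiable)")
  if (model == "sham") {
    fit <- lmerTest::lmer(aav ~ I(stage - 5) + (1 | embryo_id), data = obs,
                          REML = FALSE)
    fe <- lme4::fixef(fit)
    se <- coef(summary(fit))[, "Std. Error"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    sd_re <- vc$sdcor[vc$grp == "embryo_id"][1]
    return(list(model = "sham",
                params = sham_aav_params(phi1_s = unname(fe[1]),
                                         phi2_s = unname(fe[2]),
                                         sd_phi1_s = sd_re),
                se = c(phi1_s = unname(se[1]), phi2_s = unname(se[2])),
                logLik = as.numeric(logLik(fit)), fit = fit))
  }
  if (is.null(starts)) {
    starts <- expand.grid(phi1 = c(0.4, 0.778, 1.2),
                          phi2 = c(0.5, 1, 2),
                          phi3 = c(0.05, 0.126, 0.3))
  }
  starts <- as.matrix(starts)
  obs$embryo_id <- factor(obs$embryo_id)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      nlme::nlme(aav ~ phi1 * (plogis(0.9 * (stage - 5 - phi2)) -
                                 plogis(-0.9 * phi2)) +
                   phi3 * plogis(8 * (stage - 5.5)),
                 data = obs, fixed = phi1 + phi2 + phi3 ~ 1,
                 random = phi3 ~ 1 | embryo_id,
                 start = starts[i, c("phi1", "phi2", "phi3")],
                 control = nlme::nlmeControl(maxIter = 200, msMaxIter = 200,
                                             returnObject = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || as.numeric(logLik(fit)) > as.numeric(logLik(best)))) {
      best <- fit
    }
  }
  if (is.null(best)) stop("nonlinear mixed-effects fit failed from all ",
                          nrow(starts), " starting points")
  fe <- nlme::fixef(best)
  se <- sqrt(diag(best$varFix))
  sd_re <- as.numeric(nlme::VarCorr(best)["phi3", "StdDev"])
  list(model = "intervention",
       params = intervention_aav_params(phi1 = unname(fe["phi1"]),
                                        phi2 = unname(fe["phi2"]),
                                        phi3 = unname(fe["phi3"]),
                                        sd_phi3 = sd_re),
       se = se, logLik = as.numeric(logLik(best)), fit = best)
}
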