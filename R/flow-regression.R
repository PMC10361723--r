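# Linear mixed-effects regression of angular velocity on LRO coordinates,
# somite stage and experimental group, with per-embryo random effects:
#   aav ~ 1 + group*lr + group*pa + group*time + (1 + group | embryo_id)
# Treatment coding with Sham as reference; with three groups this gives 12
# fixed-effect coefficients and, with an unstructured 3x3 random-effect
# covariance plus residual variance, 7 covariance parameters.

#' Build the regression design frame
#'
#' Validates group levels, relevels the group factor so the reference group
#' is the baseline of the treatment coding, and centers somite stage at
#' `time_origin`.
#'
#' @param observations Data frame with `aav`, `lr`, `pa`, `stage`, `group`,
#'   `embryo_id` (e.g. from [track_summaries()]).
#' @param levels Declared group level set; the first element is the
#'   reference. Defaults to the observed levels with `"Sham"` first when
#'   present.
#' @param time_origin Stage subtracted from `stage` to form the time
#'   covariate (default 6, the first post-intervention observation stage).
#' @return Data frame with `aav`, `lr`, `pa`, `time`, `group` (factor) and
#'   `embryo_id` (factor), carrying attribute `time_origin`.
#' @export
build_design <- function(observations, levels = NULL, time_origin = 6) {
  obs <- observations
  seen <- unique(as.character(obs$group))
  if (is.null(levels)) {
    levels <- if ("Sham" %in% seen) c("Sham", setdiff(sort(seen), "Sham"))
              else sort(seen)
  }
  unknown <- setdiff(seen, levels)
  if (length(unknown)) stop("unknown group level(s): ",
                            paste(unknown, collapse = ", "))
  out <- data.frame(aav = obs$aav, lr = obs$lr, pa = obs$pa,
                    time = obs$stage - time_origin,
                    group = factor(obs$group, levels = levels),
                    embryo_id = factor(obs$embryo_id))
  attr(out, "time_origin") <- time_origin
  out
}

#' Fit the mixed-effects flow regression
#'
#' Fits `aav ~ group*lr + group*pa + group*time + (1 + group | embryo_id)`
#' (random intercept and random group effects per embryo). Inference per
#' fixed effect is Wald-t with Satterthwaite degrees of freedom. If the
#' random-effects structure is singular or fails to converge, the model is
#' downgraded to a random intercept with a warning.
#'
#' @param frame Output of [build_design()].
#' @param reml Use REML (default `TRUE`); use `FALSE` when comparing models.
#' @param alpha CI level complement (default 0.05 for 95% CIs).
#' @param random Random-effects term as character (default
#'   `"(1 + group | embryo_id)"`; reduces automatically to
#'   `"(1 | embryo_id)"` on singularity).
#' @return Object of class `flow_mixed_fit`: `coefficients` (data frame with
#'   `name`, `estimate`, `lower`, `upper`, `p_value`, `se`, `df`),
#'   `ranef_sd`, `n_obs`, `n_embryos`, `logLik`, `singular`, `fit`.
#' @export
fit_mixed_model <- function(frame, reml = TRUE, alpha = 0.05,
                            random = "(1 + group | embryo_id)") {
  one_group <- nlevels(droplevels(frame$group)) < 2
  if (one_group) random <- "(1 | embryo_id)"
  fixed <- if (one_group) "aav ~ lr + pa + time +"
           else "aav ~ group*lr + group*pa + group*time +"
  form <- as.formula(paste(fixed, random))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore",
                            calc.derivs = FALSE)
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(form, data = frame, REML = reml,
                                    control = ctrl)),
    error = function(e) NULL)
  singular <- !is.null(fit) && lme4::isSingular(fit, tol = 1e-5)
  if (is.null(fit) && random != "(1 | embryo_id)") {
    warning("random-effects structure failed to fit; downgrading to random intercept")
    form <- as.formula("aav ~ group*lr + group*pa + group*time + (1 | embryo_id)")
    fit <- suppressMessages(lmerTest::lmer(form, data = frame, REML = reml,
                                           control = ctrl))
    singular <- lme4::isSingular(fit, tol = 1e-5)
  }
  ct <- coef(summary(fit))
  est <- ct[, "Estimate"]
  se <- ct[, "Std. Error"]
  df <- ct[, "df"]
  # fall back to large-sample Wald z where Satterthwaite df is unavailable
  df[!is.finite(df) | df <= 0] <- Inf
  p <- ct[, "Pr(>|t|)"]
  p[!is.finite(p)] <- 2 * pnorm(-abs(est / se))[!is.finite(p)]
  crit <- qt(1 - alpha / 2, df)
  coefs <- data.frame(name = rownames(ct), estimate = unname(est),
                      lower = unname(est - crit * se),
                      upper = unname(est + crit * se),
                      p_value = unname(p), se = unname(se),
                      df = unname(df), row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = coefs,
                 ranef_sd = vc[is.na(vc$var2),
                               c("grp", "var1", "sdcor")],
                 n_obs = nrow(frame),
                 n_embryos = nlevels(droplevels(frame$embryo_id)),
                 logLik = as.numeric(logLik(fit)),
                 singular = singular, fit = fit),
            class = "flow_mixed_fit")
}

#' Coefficient table with significance stars
#'
#' @param fit A `flow_mixed_fit`.
#' @param alpha Unused except for interface symmetry; star thresholds are
#'   fixed at 0.001, 0.01 and 0.05.
#' @return Data frame with `name`, `estimate`, `lower`, `upper`, `p_value`,
#'   `signif` (`"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for
#'   p < 0.05, `""` otherwise).
#' @export
report_effects <- function(fit, alpha = 0.05) {
  co <- fit$coefficients
  stars <- ifelse(co$p_value < 0.001, "***",
                  ifelse(co$p_value < 0.01, "**",
                         ifelse(co$p_value < 0.05, "*", "")))
  data.frame(name = co$name, estimate = co$estimate, lower = co$lower,
             upper = co$upper, p_value = co$p_value, signif = stars,
             row.names = NULL)
}

#' @export
print.flow_mixed_fit <- function(x, ...) {
  cat("Mixed-effects flow regression: ", x$n_obs, " observations, ",
      x$n_embryos, " embryos\n", sep = "")
  if (x$singular) cat("  (singular random-effects fit)\n")
  print(report_effects(x), digits = 4)
  invisible(x)
}
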