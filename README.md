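# kupfferflow

Quantitative analysis of cilia-driven fluid flow in the zebrafish left-right
organizer (LRO, Kupffer's vesicle), and of how that flow breaks body-axis
symmetry.

The vesicle's cilia drive a counterclockwise flow whose strength varies
across the organizer and across developmental time. This package implements
the full analysis chain:

* **Track kinematics** — map particle tracks to organizer coordinates,
  compute instantaneous angular velocity (counterclockwise positive),
  tangential/radial velocity components, 8-sector angular summaries and
  12-sector directionality distributions, with core exclusion (`r < R/2`)
  and Kolmogorov-Smirnov group comparisons.
* **Flow regression** — a linear mixed-effects model of angular velocity on
  left-right position, posterior-anterior position, somite stage, and
  experimental group, with per-embryo random effects:
  `aav ~ group*lr + group*pa + group*time + (1 + group | embryo_id)`.
* **AAV recovery models** — anterior angular velocity after fluid
  extraction follows a double-logistic recovery curve
  `AAV(t) = phi1 [sigma(0.9(t-5-phi2)) - sigma(-0.9 phi2)] + phi3 sigma(8(t-5.5))`,
  while unperturbed embryos follow `0.356 + 0.0362 (t - 5)` rescaled by the
  motile-cilia fraction before 6 ss; per-embryo trajectory simulation and
  mixed-effects fitting (`nlme`, `lmerTest`) included.
* **Symmetry-breaking model** — each virtual embryo integrates
  `S = sum_t AAV(t) W(t)` over stages 3-8 ss; normal situs arises with
  probability 0.9 if `S > 1`, else 0.5. Stage-sensitivity weights `W` are
  fitted to observed defect counts by multistart maximum likelihood with
  common random numbers.
* **Situs statistics** — situs calling (solitus/inversus/heterotaxia),
  enumeration-exact two-sided Fisher test, Welch t from raw data or
  mean/SEM/n summaries, paired t, and exact Mann-Whitney.
* **Synthetic data + pipeline** — generators for tracks and outcome series
  with known ground truth, and `run_pipeline()` for reproducible YAML-driven
  end-to-end runs.

## Worked example

Simulate particle tracks for sham and ciliary-defect embryos, fit the flow
regression, then fit stage-sensitivity weights to the published
fluid-extraction outcome series:

```r
library(kupfferflow)

# simulate tracks from two groups of embryos
cfg <- flow_config(n_tracks = 12, n_frames = 8, seed = 7)
sim <- generate_tracks(cfg, list(Sham = list(),
                                 Defects = list(omega = -0.13)),
                       n_embryos = 16)

# per-track kinematic summaries and the mixed-effects flow model
obs <- track_summaries(sim$tracks, sim$meta)
fit <- fit_mixed_model(build_design(obs, levels = c("Sham", "Defects")))
print(fit)
#> Mixed-effects flow regression: 576 observations, 16 embryos
#>                name   estimate     lower     upper    p_value signif
#> 1       (Intercept)  0.2894252  0.234737  0.344113  4.559e-06    ***
#> 2      groupDefects -0.1499535 -0.223153 -0.076754  6.117e-04    ***
#> 3                lr  0.0080388  0.003683  0.012395  3.158e-04    ***
#> 4                pa  0.1613626  0.157144  0.165581 9.501e-293    ***
#> 5              time  0.0192318  0.016441  0.022023  2.874e-36    ***
#> 6   groupDefects:lr -0.0043970 -0.010698  0.001904  1.710e-01
#> 7   groupDefects:pa -0.0019008 -0.007829  0.004028  5.291e-01
#> 8 groupDefects:time  0.0007129 -0.003226  0.004652  7.223e-01

# fit stage-sensitivity weights to the published extraction outcomes
wfit <- fit_weights(extraction_outcome_series(), n_starts = 50, seed = 1)
print(wfit)
#> Stage-weight fit (log-likelihood -10.8949)
#>   weights:
#>      3      4      5      6      7      8
#> 0.7963 2.0034 1.7753 1.1982 0.0000 0.1987
#>   contributions:
#>      3      4      5      6      7      8
#> 0.0143 0.2772 0.3556 0.2949 0.0000 0.0579
#>   predicted vs observed defect rates:
#>           sham   3ss   4ss   5ss   6ss 5+7ss
#> predicted  0.1 0.148 0.271 0.349 0.148 0.380
#> observed   0.0 0.154 0.269 0.350 0.148 0.375
```

The recovered gradient along the posterior-anterior axis (`pa` ≈ 0.16
rad/s) and the defect-group offset (≈ −0.15, true value −0.13 inside the
CI) match the generating model, and the stage-weight fit places ~93% of the
normalized contribution in the 4–6 ss window with a predicted defect-rate
peak of ~35–38% for extractions hitting 5 ss — the critical period for
symmetry breaking.

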