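# Closed-form values below were computed with an independent arithmetic
# oracle: sigma(x) = 1/(1+exp(-x)) evaluated directly,
#   AAV_int(5) = 0.778*(sigma(0.9*(-0.969)) - sigma(-0.9*0.969))
#                + 0.126*sigma(8*(-0.5))  = 0.0022663
#   AAV_int(8) = 0.778*(sigma(0.9*(3-0.969)) - sigma(-0.8721))
#                + 0.126*sigma(20)        = 0.5668878
#   AAV_sham(8) = 0.356 + 3*0.0362        = 0.4646

test_that("recovery curve matches its closed form and rises from zero", {
  expect_lt(abs(intervention_mean(5) - 0.00227), 1e-3)
  expect_lt(abs(intervention_mean(8) - 0.567), 1e-3)
  expect_error(intervention_mean(4.5), "t_ref")
  # anchor: at t_ref only the late-sigmoid tail contributes
  p <- intervention_aav_params()
  expect_lte(intervention_mean(5), p$phi3 * plogis(-4) + 1e-12)
  # zero parameters give a flat zero curve
  p0 <- intervention_aav_params(phi1 = 0, phi3 = 0)
  expect_equal(intervention_mean(c(5, 6, 7, 8), p0, phi3_draw = 0),
               rep(0, 4))
  # nondecreasing in t for nonnegative phi1, phi3
  tt <- seq(5, 8, by = 0.05)
  expect_true(all(diff(intervention_mean(tt)) >= 0))
})

test_that("sham model is linear in stage", {
  expect_equal(sham_mean(5), 0.356)
  expect_equal(sham_mean(8), 0.4646)
  p <- sham_aav_params(phi2_s = 0)
  expect_equal(sham_mean(3:8, p), rep(0.356, 6))
})

test_that("motile-cilia rescaling follows the stage fractions", {
  expect_equal(rescale_early(0.763, 3), 0.0557, tolerance = 1e-10)
  expect_equal(rescale_early(0, 4), 0)
  expect_error(rescale_early(0.5, 6), "3, 4, 5")
  v <- rescale_early(0.4, c(3, 4, 5))
  expect_true(all(diff(v) > 0))
  expect_error(motile_cilia_fractions(c(`3` = 50, `4` = 40, `5` = 60,
                                        `6` = 70)), "increasing")
})

test_that("trajectories compose sham, recovery and rescaling correctly", {
  ip <- intervention_aav_params(sd_phi3 = 0)
  sp <- sham_aav_params(sd_phi1_s = 0)
  fr <- motile_cilia_fractions()
  pct <- fr$percent

  sham <- sample_trajectory(intervention_scenario("sham"), ip, sp, seed = 1)
  a6 <- sham_mean(6, sp)
  expect_equal(unname(sham[c("3", "4", "5")]),
               unname(pct[c("3", "4", "5")] / pct["6"] * a6))
  expect_equal(unname(sham[c("6", "7", "8")]), sham_mean(6:8, sp))
  expect_true(all(diff(sham) > 0))

  # extraction at 5 ss: sham before, recovery curve from 5 ss on
  tr5 <- sample_trajectory(intervention_scenario("5ss", 5), ip, sp, seed = 1)
  expect_equal(unname(tr5[c("3", "4")]), unname(sham[c("3", "4")]))
  expect_lt(tr5["5"], 0.01)
  expect_equal(unname(tr5[c("6", "7", "8")]), intervention_mean(6:8, ip))
  expect_true(tr5["6"] < tr5["7"] && tr5["7"] < tr5["8"])

  # extraction at 3 ss: time-shifted curve, rescaled up to 5 ss
  tr3 <- sample_trajectory(intervention_scenario("3ss", 3), ip, sp, seed = 1)
  shifted <- intervention_mean(3:8 + 2, ip)
  expect_equal(unname(tr3[c("3", "4", "5")]),
               unname(shifted[1:3] * pct[c("3", "4", "5")] / pct["6"]))
  expect_equal(unname(tr3[c("6", "7", "8")]), shifted[4:6])

  # double extraction 5 + 7 ss: recovery restarts at 7 ss
  trd <- sample_trajectory(intervention_scenario("5+7ss", c(5, 7)), ip, sp,
                           seed = 1)
  expect_equal(unname(trd[c("3", "4", "5", "6")]),
               unname(tr5[c("3", "4", "5", "6")]))
  expect_lt(trd["7"], 0.01)
  expect_equal(unname(trd["8"]), intervention_mean(6, ip))

  # an extraction after the window leaves the trajectory unchanged
  tr12 <- sample_trajectory(intervention_scenario("12ss", 12), ip, sp,
                            seed = 1)
  expect_equal(tr12, sham)
})

test_that("trajectory sampling is reproducible and respects random effects", {
  sc <- intervention_scenario("5ss", 5)
  a <- sample_trajectories(50, sc, seed = 9)
  b <- sample_trajectories(50, sc, seed = 9)
  expect_identical(a, b)
  # with positive SDs, embryos differ
  expect_gt(sd(a[, "8"]), 0)
  # zero-variance parameters give identical embryos
  z <- sample_trajectories(10, sc, intervention_aav_params(sd_phi3 = 0),
                           sham_aav_params(sd_phi1_s = 0), seed = 2)
  expect_equal(max(apply(z, 2, sd)), 0)
})

test_that("model fitting recovers generating parameters", {
  # noiseless sham data: exact recovery of intercept and slope
  sp <- sham_aav_params(sd_phi1_s = 0)
  obs <- expand.grid(embryo_id = sprintf("E%02d", 1:8), stage = 5:8)
  obs$aav <- sham_mean(obs$stage, sp)
  fit <- suppressWarnings(fit_aav_model(obs, "sham"))
  expect_equal(fit$params$phi1_s, 0.356, tolerance = 1e-6)
  expect_equal(fit$params$phi2_s, 0.0362, tolerance = 1e-6)

  # sham data with random intercepts and noise: recovery within 2 SE
  set.seed(12)
  n_emb <- 20
  obs <- expand.grid(embryo_id = sprintf("E%02d", 1:n_emb), stage = 5:8)
  b <- rnorm(n_emb, 0, 0.0378)
  names(b) <- sprintf("E%02d", 1:n_emb)
  obs$aav <- sham_mean(obs$stage, phi1_draw = 0.356 + b[obs$embryo_id]) +
    rnorm(nrow(obs), 0, 0.02)
  fit <- fit_aav_model(obs, "sham")
  expect_lt(abs(fit$params$phi1_s - 0.356), 2 * fit$se["phi1_s"])
  expect_lt(abs(fit$params$phi2_s - 0.0362), 2 * fit$se["phi2_s"])

  # intervention data simulated at the default parameters
  set.seed(13)
  ip <- intervention_aav_params()
  phi3 <- rnorm(20, ip$phi3, ip$sd_phi3)
  obs <- expand.grid(embryo_id = sprintf("E%02d", 1:20), stage = 5:8)
  obs$aav <- intervention_mean(obs$stage, ip,
                               phi3_draw = phi3[as.integer(factor(obs$embryo_id))]) +
    rnorm(nrow(obs), 0, 0.03)
  fit <- fit_aav_model(obs, "intervention")
  expect_lt(abs(fit$params$phi1 - ip$phi1), 2.5 * fit$se["phi1"])
  expect_lt(abs(fit$params$phi3 - ip$phi3), 2.5 * fit$se["phi3"])

  # single-stage data is unidentifiable
  one <- data.frame(embryo_id = sprintf("E%02d", 1:6), stage = 6,
                    aav = rnorm(6, 0.3, 0.01))
  expect_error(fit_aav_model(one, "sham"), "2 stages")
  few <- obs[obs$embryo_id %in% sprintf("E%02d", 1:3), ]
  expect_error(fit_aav_model(few, "intervention"), "5 embryos")
})
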