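test_that("error metrics match hand-computed values", {
  obs <- data.frame(year = 1:3, amount_hkd = c(100, 200, 400))
  sim <- data.frame(year = 1:3, amount_hkd = c(90, 220, 400))
  expect_equal(mape(sim, obs), mean(c(10, 10, 0)))
  expect_equal(mape(obs, obs), 0)
  obs2 <- data.frame(year = 1:3, amount_hkd = c(1, 2, 3))
  sim2 <- data.frame(year = 1:3, amount_hkd = c(1.1, 1.9, 3.0))
  expect_equal(r_squared(sim2, obs2), 0.99)
  expect_equal(r_squared(obs2, obs2), 1)
  # predicting the observed mean gives exactly zero
  simflat <- data.frame(year = 1:3, amount_hkd = rep(2, 3))
  expect_equal(r_squared(simflat, obs2), 0)
})

test_that("metrics are permutation- and scale-invariant as appropriate", {
  obs <- data.frame(year = 2009:2014, amount_hkd = c(5, 8, 13, 20, 28, 40))
  sim <- data.frame(year = 2009:2014, amount_hkd = c(6, 7, 14, 19, 30, 38))
  shuffled <- sim[c(4, 1, 6, 2, 5, 3), ]
  expect_equal(mape(shuffled, obs), mape(sim, obs))
  expect_equal(r_squared(shuffled, obs), r_squared(sim, obs))
  scaled <- function(d, k) transform(d, amount_hkd = amount_hkd * k)
  expect_equal(mape(scaled(sim, 1e6), scaled(obs, 1e6)), mape(sim, obs))
})

test_that("degenerate series are rejected", {
  obs <- data.frame(year = 1:2, amount_hkd = c(0, 5))
  sim <- data.frame(year = 1:2, amount_hkd = c(1, 5))
  expect_error(mape(sim, obs), "undefined")
  expect_error(mape(sim, data.frame(year = 3:4, amount_hkd = c(1, 2))),
               "same years")
  flat <- data.frame(year = 1:2, amount_hkd = c(5, 5))
  expect_error(r_squared(sim, flat), "constant")
})

test_that("parameter overrides keep fixture invariants intact", {
  fx <- test_fixture()
  fx2 <- set_fixture_param(fx, "uptake.w_max", 0.6)
  expect_equal(fx2$uptake$w_max, 0.6)
  fx3 <- set_fixture_param(fx, "substitution.from_public", 0.7)
  s <- fx3$substitution
  expect_equal(s$from_public + s$from_private + s$induced, 1)
  fx4 <- set_fixture_param(fx, "visit_rate.b70plus.scale", 1.1)
  expect_equal(fx4$demography$visit_rate$b70plus,
               fx$demography$visit_rate$b70plus * 1.1)
  expect_error(set_fixture_param(fx, "nope.nope", 1), "unknown")
})

test_that("noiseless self-fit recovers the truth with near-zero MAPE", {
  fx <- hk_anchor_fixture(check = FALSE)
  obs <- synthetic_expenditure(fx, list(uptake.w_max = 0.6), noise_cv = 0)
  spec <- calibration_spec(fx, free = list(uptake.w_max = c(0.3, 0.95)),
                           end_year = 2016)
  fit <- fit_parameters(spec, observed = obs)
  expect_lt(abs(fit$fitted[["uptake.w_max"]] - 0.6), 0.01)
  expect_lt(fit$mape, 1)
  expect_true(fit$accepted)
  expect_gt(fit$r_squared, 0.99)
})

test_that("fits respect bounds and never fall above their start points", {
  fx <- test_fixture()
  obs <- synthetic_expenditure(fx, list(uptake.w_max = 0.55,
                                        substitution.from_public = 0.5),
                               noise_cv = 0.1, seed = 11)
  spec <- calibration_spec(
    fx, free = list(uptake.w_max = c(0.3, 0.9),
                    substitution.from_public = c(0.1, 0.8)),
    end_year = 2016, n_starts = 2, max_evaluations = 60, seed = 5)
  fit <- fit_parameters(spec, observed = obs)
  expect_true(fit$fitted[["uptake.w_max"]] >= 0.3 &&
                fit$fitted[["uptake.w_max"]] <= 0.9)
  expect_true(all(fit$objective <= fit$start_objectives))
})

test_that("anchor penalties pull the fit towards trajectory targets", {
  fx <- hk_anchor_fixture(check = FALSE)
  target <- 0.70
  spec <- calibration_spec(fx,
                           free = list(public_share.under60 = c(0.25, 0.5)),
                           end_year = 2032)
  fit <- fit_parameters(spec, anchors = list(ratio_2018 = target))
  out <- run_scenario(simulation_config(fit$fixture, "baseline"))$annual
  achieved <- out$ratio_public_private[out$year == 2018]
  expect_lt(abs(achieved - target), 0.02)
})
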