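test_that("synthetic fixtures are reproducible and validated", {
  f1 <- generate_synthetic_fixture(123)
  f2 <- generate_synthetic_fixture(123)
  expect_identical(f1, f2)
  expect_false(identical(f1, generate_synthetic_fixture(124)))
  expect_error(generate_synthetic_fixture(1, scale = 0), "positive")
  expect_s3_class(validate_fixture(f1), "ehcv_fixture")
})

test_that("generated bundles respect structural constraints over seeds", {
  for (seed in 1:100) {
    fx <- generate_synthetic_fixture(seed, scale = 1e5)
    ps <- fx$demography$public_share
    # public reliance increases with age band
    expect_true(all(ps$b70plus >= ps$under60), info = seed)
    # mortality improves over calendar time
    expect_true(all(diff(fx$demography$death_rate$b70plus) <= 0),
                info = seed)
    # monotone utilization curve anchored at zero
    expect_true(!is.unsorted(fx$chronic$curve$visits), info = seed)
    expect_equal(fx$chronic$curve$visits[1], 0)
  }
})

test_that("fixture JSON round-trips through serialization", {
  fx <- test_fixture()
  fx$observed_expenditure <- data.frame(year = 2009:2012,
                                        amount_hkd = c(1e6, 2e6, 4e6, 8e6))
  path <- withr::local_tempfile(fileext = ".json")
  write_fixture_json(fx, path)
  back <- read_fixture_json(path)
  expect_equal(back$initial_population, fx$initial_population)
  expect_equal(back$demography, fx$demography)
  expect_equal(back$mix, fx$mix)
  expect_equal(back$chronic, fx$chronic)
  expect_equal(back$observed_expenditure, fx$observed_expenditure)
  # identical runs from the round-tripped bundle
  o1 <- run_scenario(simulation_config(fx, "baseline", end_year = 2012))
  o2 <- run_scenario(simulation_config(back, "baseline", end_year = 2012))
  expect_equal(o1$annual, o2$annual)
})

test_that("noise-free synthetic expenditure matches the model exactly", {
  fx <- test_fixture()
  obs <- synthetic_expenditure(fx, list(uptake.w_max = 0.7), noise_cv = 0)
  fx7 <- set_fixture_param(fx, "uptake.w_max", 0.7)
  out <- run_scenario(simulation_config(fx7, "baseline", end_year = 2016))
  sim <- data.frame(year = obs$year,
                    amount_hkd = out$annual$expenditure_hkd[
                      out$annual$year %in% obs$year])
  expect_equal(mape(sim, obs), 0)
})

test_that("noisy series are reproducible with mean-one noise", {
  fx <- test_fixture()
  s1 <- synthetic_expenditure(fx, noise_cv = 0.05, seed = 9)
  s2 <- synthetic_expenditure(fx, noise_cv = 0.05, seed = 9)
  expect_identical(s1, s2)
  clean <- synthetic_expenditure(fx, noise_cv = 0, years = 2009:2010)
  ratios <- unlist(lapply(1:100, function(s) {
    noisy <- synthetic_expenditure(fx, noise_cv = 0.05, seed = s,
                                   years = 2009:2010)
    noisy$amount_hkd / clean$amount_hkd
  }))
  expect_equal(mean(ratios), 1, tolerance = 0.01)
})

test_that("the packaged HK fixture passes its anchor self-check", {
  res <- check_hk_fixture(hk_anchor_fixture(check = FALSE))
  expect_true(all(res$pass))
  expect_s3_class(hk_anchor_fixture(check = TRUE), "ehcv_fixture")
})

test_that("the HK baseline calibration clears the published fitness bar", {
  fx <- hk_anchor_fixture(check = FALSE)
  out <- run_scenario(simulation_config(fx, "baseline"))$annual
  sim <- data.frame(year = out$year, amount_hkd = out$expenditure_hkd)
  sim <- sim[sim$year %in% fx$observed_expenditure$year, ]
  expect_lt(mape(sim, fx$observed_expenditure), 40)
  expect_gt(r_squared(sim, fx$observed_expenditure), 0.9)
})
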