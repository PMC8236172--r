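test_that("runs are deterministic and bit-identical", {
  fx <- test_fixture()
  o1 <- run_scenario(simulation_config(fx, "amount_escalation"))
  o2 <- run_scenario(simulation_config(fx, "amount_escalation"))
  expect_identical(o1$annual, o2$annual)
})

test_that("a zero-amount policy reproduces pure demography", {
  fx <- test_fixture()
  off <- run_scenario(simulation_config(fx, zero_policy()))$annual
  # pure demography reference: willingness 0 means vouchers never used
  fx0 <- fx
  fx0$uptake <- uptake_params(0, 0, 2010)
  ref <- run_scenario(simulation_config(fx0, "baseline"))$annual
  expect_equal(off$visits_public, ref$visits_public, tolerance = 1e-12)
  expect_equal(off$visits_private, ref$visits_private, tolerance = 1e-12)
  expect_equal(sum(off$expenditure_hkd), 0)
  # and the split equals the banded totals exactly
  expect_equal(off$visits_public + off$visits_private, off$visits_total,
               tolerance = 1e-12)
})

test_that("weekly flows sum exactly to the reported annual totals", {
  fx <- test_fixture()
  out <- run_scenario(simulation_config(fx, "baseline", start_year = 2009,
                                        end_year = 2010))$annual
  st <- population_state(fx$initial_population)
  acc <- c(public = 0, private = 0, expenditure = 0)
  for (w in 0:51) {
    step <- integrate_week(st, fx, baseline_policy(), week = w)
    acc["public"] <- acc["public"] + step$flows$public
    acc["private"] <- acc["private"] + step$flows$private
    acc["expenditure"] <- acc["expenditure"] + step$flows$expenditure
    st <- step$state
  }
  expect_equal(unname(acc["public"]), out$visits_public[1])
  expect_equal(unname(acc["private"]), out$visits_private[1])
  expect_equal(unname(acc["expenditure"]), out$expenditure_hkd[1])
  expect_equal(st$counts[["b70plus"]], out$pop_70plus[1])
})

test_that("pre-scheme weeks carry no voucher flows", {
  fx <- test_fixture()
  fx$start_year <- 2005L
  st <- population_state(fx$initial_population)
  step <- integrate_week(st, fx, baseline_policy(), week = 10)
  expect_equal(sum(step$flows$voucher_cat), 0)
  expect_equal(step$flows$v_chronic, 0)
  expect_equal(step$flows$public + step$flows$private,
               sum(step$flows$total), tolerance = 1e-12)
})

test_that("a zero-population fixture yields an all-zero flagged series", {
  fx <- test_fixture()
  fx$initial_population[] <- 0
  fx$demography$birth_inflow[] <- 0
  out <- run_scenario(simulation_config(fx, "baseline"))$annual
  expect_true(all(out$visits_total == 0))
  expect_true(all(is.na(out$ratio_public_private)))
})

test_that("scenario comparison is zero against itself and validated", {
  fx <- test_fixture()
  cfg <- function(s) simulation_config(fx, s)
  cmp <- compare_scenarios(list(cfg("baseline"), cfg("baseline")))
  expect_true(all(cmp$d_public_visits == 0))
  expect_true(all(cmp$d_ratio == 0))
  cmp2 <- compare_scenarios(list(cfg("baseline"), cfg("chronic_voucher")))
  chronic_rows <- cmp2[cmp2$scenario == "chronic_voucher" &
                         cmp2$year >= 2021, ]
  expect_true(all(chronic_rows$d_public_visits < 0))
  short <- simulation_config(fx, "baseline", end_year = 2020)
  expect_error(compare_scenarios(list(cfg("baseline"), short)), "horizon")
})

test_that("dt must divide the model year and halving dt barely moves output", {
  fx <- test_fixture()
  expect_error(simulation_config(fx, "baseline", dt = 3), "divide")
  o1 <- run_scenario(simulation_config(fx, "baseline", dt = 1))$annual
  o2 <- run_scenario(simulation_config(fx, "baseline", dt = 0.5))$annual
  expect_equal(o1$visits_public, o2$visits_public, tolerance = 0.01)
})
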