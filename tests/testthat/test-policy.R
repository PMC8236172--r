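test_that("the packaged baseline reproduces the historical schedule", {
  pol <- baseline_policy()
  want <- list(`2008` = c(0, 70), `2009` = c(250, 70), `2011` = c(250, 70),
               `2012` = c(500, 70), `2013` = c(1000, 70),
               `2014` = c(2000, 70), `2016` = c(2000, 70),
               `2017` = c(2000, 65), `2018` = c(2000, 65),
               `2032` = c(2000, 65))
  for (y in names(want)) {
    ep <- policy_at(pol, as.integer(y))
    expect_equal(c(ep$annual_amount, ep$eligibility_age), unname(want[[y]]),
                 info = y)
  }
  # carry-forward arrives with the 2014 increase
  expect_equal(policy_at(pol, 2013)$carry_cap, 0)
  expect_equal(policy_at(pol, 2014)$carry_cap, 4000)
})

test_that("policy lookup is piecewise-constant between epoch starts", {
  pol <- baseline_policy()
  starts <- vapply(pol$epochs, `[[`, integer(1), "start_year")
  for (y in 2009:2032) {
    ep <- policy_at(pol, y)
    expect_identical(ep, policy_at(pol, max(starts[starts <= y])))
  }
})

test_that("carry-forward caps the accumulated balance", {
  expect_equal(carry_forward(3000, 2000, 4000), 4000)
  expect_equal(carry_forward(1500, 2000, 4000), 3500)
  expect_equal(carry_forward(0, 2000, 4000), 2000)
  # cap 0 disables carry-forward entirely
  expect_equal(carry_forward(1500, 2000, 0), 2000)
  expect_error(carry_forward(-1, 2000, 4000), ">= 0")
})

test_that("scenario application overrides epochs without touching baseline", {
  base <- baseline_policy()
  amt <- apply_scenario(base, ehcv_scenario("amount_escalation"))
  expect_equal(policy_at(amt, 2021)$annual_amount, 3000)
  expect_equal(policy_at(amt, 2025)$annual_amount, 4000)
  expect_equal(policy_at(amt, 2029)$annual_amount, 5000)
  expect_equal(policy_at(amt, 2020)$annual_amount, 2000)
  # carry cap rises with amounts above $4000
  expect_equal(policy_at(amt, 2029)$carry_cap, 5000)
  expect_equal(policy_at(amt, 2021)$carry_cap, 4000)

  age <- apply_scenario(base, ehcv_scenario("age_lowering"))
  expect_equal(policy_at(age, 2021)$eligibility_age, 60)
  expect_equal(policy_at(age, 2021)$annual_amount, 2000)
  expect_equal(policy_at(age, 2020)$eligibility_age, 65)

  chr <- apply_scenario(base, ehcv_scenario("chronic_voucher"))
  expect_equal(chr$chronic_amount, 2000)
  expect_equal(chr$chronic_start_year, 2021L)

  # baseline untouched, identity and idempotence
  expect_identical(base, baseline_policy())
  expect_identical(apply_scenario(base, ehcv_scenario("baseline")), base)
  expect_identical(apply_scenario(amt, ehcv_scenario("amount_escalation")),
                   amt)
})

test_that("invalid scenario events are rejected", {
  expect_error(scenario_spec("x", data.frame(year = 2021,
                                             attribute = "carry_cap",
                                             value = 1)), "unknown")
  expect_error(scenario_spec("x", data.frame(year = 2005,
                                             attribute = "annual_amount",
                                             value = 1000)), "2009")
  expect_error(policy_epoch(2020, 2000, 68), "eligibility_age")
  expect_error(policy_epoch(2020, 2000, 70, carry_cap = 1500),
               "carry_cap")
})
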