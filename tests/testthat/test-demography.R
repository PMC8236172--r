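test_that("Euler step reduces to identity with all rates zero", {
  st <- population_state(c(under60 = 1e4, b60_64 = 2e3, b65_69 = 1e3,
                           b70plus = 500), week_index = 3)
  rt <- demography_rates()
  out <- step_population(st, rt, dt = 1)
  expect_identical(out$counts, st$counts)
  expect_equal(out$week_index, 4)
})

test_that("single-band mortality follows the geometric recurrence exactly", {
  # independent closed form: N0 (1 - mu dt)^n for the same recurrence
  mu <- 0.001
  st <- population_state(c(under60 = 1e4, b60_64 = 0, b65_69 = 0,
                           b70plus = 0))
  rt <- demography_rates(death_rate = c(mu, 0, 0, 0))
  for (i in 1:52) st <- step_population(st, rt)
  expect_equal(st$counts[["under60"]], 1e4 * (1 - mu)^52, tolerance = 1e-12)
  expect_equal(st$counts[["under60"]], 9493.04, tolerance = 1e-5)
})

test_that("aging transfers conserve the total population", {
  st <- population_state(c(under60 = 5e5, b60_64 = 4e4, b65_69 = 3e4,
                           b70plus = 6e4))
  rt <- demography_rates(aging_rate = c(0.001, 1 / 260, 1 / 260, 0))
  total0 <- sum(st$counts)
  for (i in 1:200) st <- step_population(st, rt)
  expect_equal(sum(st$counts), total0, tolerance = 1e-9)
})

test_that("a step driving a stock negative raises, never clamps", {
  st <- population_state(c(under60 = 100, b60_64 = 0, b65_69 = 0,
                           b70plus = 0))
  rt <- demography_rates(aging_rate = c(0.9, 0, 0, 0),
                         death_rate = c(0.2, 0, 0, 0))
  expect_error(step_population(st, rt, dt = 1), "under60")
  expect_error(demography_rates(death_rate = c(NA, 0, 0, 0)), "finite")
})

test_that("visit generation is the count-rate product and splits add up", {
  st <- population_state(c(under60 = 1000, b60_64 = 0, b65_69 = 0,
                           b70plus = 0))
  rt <- demography_rates(visit_rate = c(0.1, 0, 0, 0),
                         public_share = 0.42)
  fl <- split_public_private(generate_visits(st, rt), rt)
  expect_equal(unname(fl$total), c(100, 0, 0, 0))
  expect_equal(fl$public_base[["under60"]], 42)
  expect_equal(fl$private_base[["under60"]], 58)
  expect_equal(fl$public_base + fl$private_base, fl$total)

  # symmetry and degenerate shares
  rt2 <- demography_rates(visit_rate = 0.1, public_share = 0.5)
  st2 <- population_state(rep(1000, 4))
  fl2 <- split_public_private(generate_visits(st2, rt2), rt2)
  expect_equal(fl2$public_base, fl2$private_base)
  rt3 <- demography_rates(visit_rate = 0.1, public_share = 0)
  fl3 <- split_public_private(generate_visits(st2, rt3), rt3)
  expect_equal(unname(fl3$public_base), rep(0, 4))
  expect_error(demography_rates(public_share = 1.2), "\\[0, 1\\]")
})

test_that("zero population generates zero visits everywhere", {
  st <- population_state(rep(0, 4))
  rt <- demography_rates(visit_rate = c(2, 3, 4, 5) / 52)
  expect_equal(unname(generate_visits(st, rt)$total), rep(0, 4))
})

test_that("splits stay consistent along a full simulated horizon", {
  fx <- test_fixture()
  st <- population_state(fx$initial_population)
  for (w in seq(0, 259, by = 1)) {
    yr <- 2009 + w %/% 52
    rt <- ehcvsim:::rates_for_year(fx, yr)
    fl <- split_public_private(generate_visits(st, rt), rt)
    expect_equal(fl$public_base + fl$private_base, fl$total,
                 tolerance = 1e-12)
    st <- step_population(st, rt)
  }
})

test_that("halving the step changes the 2032 population by under 1%", {
  fx <- hk_anchor_fixture(check = FALSE)
  pops <- function(dt) {
    a <- run_scenario(simulation_config(fx, "baseline", dt = dt))$annual
    unlist(a[a$year == 2032, c("pop_under60", "pop_60_64", "pop_65_69",
                               "pop_70plus")])
  }
  p1 <- pops(1)
  p2 <- pops(0.5)
  expect_true(all(abs(p1 - p2) / p2 < 0.01))
})

test_that("Euler error shrinks first order in the step size", {
  mu <- 0.004
  run <- function(dt) {
    st <- population_state(c(under60 = 1e4, b60_64 = 0, b65_69 = 0,
                             b70plus = 0))
    rt <- demography_rates(death_rate = c(mu, 0, 0, 0))
    for (i in seq_len(52 / dt)) st <- step_population(st, rt, dt)
    st$counts[["under60"]]
  }
  exact <- 1e4 * exp(-mu * 52)
  err1 <- abs(run(1) - exact)
  err2 <- abs(run(0.5) - exact)
  expect_equal(err1 / err2, 2, tolerance = 0.1)
})
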