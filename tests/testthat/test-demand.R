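test_mix <- function(weight = c(1, 0, 0, 0, 0), price = 330, infl = 0) {
  service_mix(weight, base_price = price, inflation_rate = infl,
              reference_year = 2009)
}

test_that("price inflation is geometric and validated", {
  expect_equal(inflate_price(260, 2016, 2018, 0.03), 260 * 1.03^2)
  expect_equal(inflate_price(260, 2016, 2018, 0.03), 275.834)
  expect_equal(inflate_price(500, 2010, 2030, 0), 500)
  expect_error(inflate_price(260, 2016, 2015, 0.03), "precede")
})

test_that("HK fixture claim prices sit in the published ranges", {
  mix <- hk_anchor_fixture(check = FALSE)$mix
  for (y in 2016:2019) {
    p <- inflate_price(mix$base_price, mix$reference_year, y,
                       mix$inflation_rate)
    expect_gt(p[["non_preventive"]], 260)   # GP claims $260-$330
    expect_lt(p[["non_preventive"]], 330)
    expect_gt(p[["other"]], 1600)           # optometry claims $1600-$1951
    expect_lt(p[["other"]], 1951)
  }
})

test_that("budget-share demand divides entitlement dollars by price", {
  eligible <- c(under60 = 0, b60_64 = 0, b65_69 = 0, b70plus = 1000)
  ev <- expected_voucher_visits(eligible, 2000, test_mix(), 2009)
  expect_equal(ev$total, 1000 * 2000 / 330, tolerance = 1e-12)
  expect_equal(ev$total, 6060.6, tolerance = 1e-4)

  # zero entitlement, equal split across equal-priced categories
  expect_equal(expected_voucher_visits(eligible, 0, test_mix(), 2015)$total,
               0)
  mix2 <- test_mix(weight = c(0.5, 0.5, 0, 0, 0), price = 300)
  ev2 <- expected_voucher_visits(eligible, 2000, mix2, 2009)
  expect_equal(ev2$visits[, "non_preventive"],
               ev2$visits[, "chronic_follow_up"])
})

test_that("voucher dollars are conserved across categories", {
  fx <- test_fixture()
  eligible <- c(under60 = 0, b60_64 = 0, b65_69 = 5e4, b70plus = 2e5)
  for (year in c(2009, 2015, 2025)) {
    ev <- expected_voucher_visits(eligible, 2000, fx$mix, year)
    prices <- inflate_price(fx$mix$base_price, fx$mix$reference_year, year,
                            fx$mix$inflation_rate)
    spent <- sum(colSums(ev$visits) * prices)
    expect_equal(spent, sum(eligible) * 2000, tolerance = 1e-6)
  }
})

test_that("expected visits rise with entitlement and fall with prices", {
  fx <- test_fixture()
  eligible <- c(under60 = 0, b60_64 = 0, b65_69 = 5e4, b70plus = 2e5)
  totals <- vapply(seq(0, 4000, by = 500), function(e) {
    expected_voucher_visits(eligible, e, fx$mix, 2015)$total
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))

  dearer <- fx$mix
  dearer$base_price <- dearer$base_price * 1.3
  expect_lt(expected_voucher_visits(eligible, 2000, dearer, 2015)$total,
            expected_voucher_visits(eligible, 2000, fx$mix, 2015)$total)
})

test_that("positive inflation erodes visits year over year", {
  mix <- test_mix(price = 300, infl = 0.03)
  eligible <- c(under60 = 0, b60_64 = 0, b65_69 = 0, b70plus = 1000)
  totals <- vapply(2009:2020, function(y) {
    expected_voucher_visits(eligible, 2000, mix, y)$total
  }, numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("degenerate mixes are rejected", {
  expect_error(service_mix(c(0.5, 0.5, 0.5, 0, 0), 300), "sum to 1")
  expect_error(service_mix(c(1, 0, 0, 0, 0), 0), "> 0")
})
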