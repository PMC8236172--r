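# shared fixtures and memoised scenario runs for the test suite

.test_cache <- new.env(parent = emptyenv())

# small deterministic synthetic bundle for fast engine-level tests
test_fixture <- function(seed = 7) {
  key <- sprintf("fx_%d", seed)
  if (is.null(.test_cache[[key]])) {
    .test_cache[[key]] <- generate_synthetic_fixture(seed, scale = 1e6)
  }
  .test_cache[[key]]
}

# memoised annual output of a packaged scenario on the HK anchored fixture
hk_run <- function(scenario = "baseline") {
  key <- sprintf("hk_%s", scenario)
  if (is.null(.test_cache[[key]])) {
    fx <- hk_anchor_fixture(check = FALSE)
    .test_cache[[key]] <-
      run_scenario(simulation_config(fx, scenario))$annual
  }
  .test_cache[[key]]
}

hk_at <- function(annual, year, col) annual[annual$year == year, col]

# a policy with every amount zero: vouchers never flow
zero_policy <- function() voucher_policy(policy_epoch(2009, 0, 70, 0))

expect_rel <- function(actual, target, tol) {
  expect_lt(abs(actual - target) / abs(target), tol)
}
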