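#' Generate a fully synthetic stress-test fixture
#'
#' Draws a random but internally consistent input bundle for property
#' testing: an aging population (death rates declining over calendar time,
#' positive aging flows), public reliance increasing with age band, a
#' monotone chronic utilization curve, and a plausible voucher service
#' mix. The same seed always yields an identical bundle.
#'
#' @param seed Integer seed.
#' @param scale Approximate total population size in persons (> 0).
#' @return A validated `ehcv_fixture` with provenance `synthetic`.
#' @export
generate_synthetic_fixture <- function(seed, scale = 1e6) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("'scale' must be a single positive population size", call. = FALSE)
  }
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  years <- 2009:2032
  n <- length(years)
  decline <- seq(1, stats::runif(1, 0.75, 0.9), length.out = n)
  const <- function(x) rep(x, n)

  init <- c(under60 = stats::runif(1, 0.72, 0.85),
            b60_64 = stats::runif(1, 0.04, 0.06),
            b65_69 = stats::runif(1, 0.03, 0.05),
            b70plus = stats::runif(1, 0.07, 0.12))
  init <- init / sum(init) * scale

  s1 <- stats::runif(1, 0.2, 0.4)
  shares <- cumsum(c(s1, stats::runif(3, 0.02, 0.15)))
  shares <- pmin(shares, 0.95)

  prev <- cumsum(c(stats::runif(1, 0.08, 0.18), stats::runif(3, 0.08, 0.16)))
  prev <- pmin(prev, 0.9)

  u2000 <- stats::runif(1, 3, 5)
  curve <- data.frame(amount = c(0, 2000, 4000),
                      visits = c(0, u2000, u2000 + stats::runif(1, 0.5, 2)))

  w <- stats::rgamma(5, shape = c(8, 4, 2, 1, 2))
  sub <- stats::rgamma(3, shape = c(8, 6, 4))
  sub_c <- stats::rgamma(3, shape = c(12, 2, 2))

  demography <- list(
    years = years,
    birth_inflow = const(scale * stats::runif(1, 0.008, 0.012)),
    death_rate = list(under60 = stats::runif(1, 0.002, 0.004) * decline,
                      b60_64 = stats::runif(1, 0.006, 0.01) * decline,
                      b65_69 = stats::runif(1, 0.01, 0.018) * decline,
                      b70plus = stats::runif(1, 0.05, 0.07) * decline),
    aging_rate = list(under60 = stats::runif(1, 0.01, 0.02) *
                        seq(1, stats::runif(1, 1.1, 1.5), length.out = n),
                      b60_64 = const(0.2), b65_69 = const(0.2),
                      b70plus = const(0)),
    visit_rate = list(under60 = const(stats::runif(1, 2, 3.5)),
                      b60_64 = const(stats::runif(1, 3, 5)),
                      b65_69 = const(stats::runif(1, 4, 7)),
                      b70plus = const(stats::runif(1, 8, 14))),
    public_share = list(under60 = const(shares[1L]),
                        b60_64 = const(shares[2L]),
                        b65_69 = const(shares[3L]),
                        b70plus = const(shares[4L])))

  fixture_bundle(
    start_year = 2009,
    initial_population = init,
    demography = demography,
    mix = service_mix(w / sum(w),
                      base_price = c(stats::runif(1, 250, 350),
                                     stats::runif(1, 300, 420),
                                     stats::runif(1, 800, 1500),
                                     stats::runif(1, 200, 400),
                                     stats::runif(1, 800, 1800)),
                      inflation_rate = stats::runif(1, 0.01, 0.04),
                      reference_year = 2009),
    uptake = uptake_params(stats::runif(1, 0.5, 0.9),
                           stats::runif(1, 0.3, 0.7),
                           stats::runif(1, 2010, 2014)),
    substitution = substitution_params(sub[1L] / sum(sub),
                                       sub[2L] / sum(sub),
                                       1 - (sub[1L] + sub[2L]) / sum(sub)),
    chronic = chronic_params(prev, curve,
                             price = stats::runif(1, 300, 500)),
    chronic_substitution = substitution_params(
      sub_c[1L] / sum(sub_c), sub_c[2L] / sum(sub_c),
      1 - (sub_c[1L] + sub_c[2L]) / sum(sub_c)),
    carry_release = 0.5,
    provenance = c(initial_population = "synthetic",
                   demography = "synthetic", mix = "synthetic",
                   uptake = "synthetic", substitution = "synthetic",
                   chronic = "synthetic"),
    meta = list(name = sprintf("synthetic-%d", as.integer(seed)),
                seed = as.integer(seed), scale = scale))
}

#' Simulate a noisy observed expenditure series
#'
#' Runs the model at known parameter values and perturbs each annual
#' expenditure with mean-one multiplicative lognormal noise of a given
#' coefficient of variation. With `noise_cv = 0` the series equals the
#' model output exactly, which makes parameter-recovery tests for the
#' calibration module possible.
#'
#' @param fixture An `ehcv_fixture`.
#' @param true_params Named list of parameter overrides (see
#'   [set_fixture_param()]) defining the ground truth.
#' @param noise_cv Coefficient of variation of the noise (>= 0).
#' @param seed Integer seed for the noise draw.
#' @param years Years of the series (default the 2009--2016 calibration
#'   window).
#' @param policy Policy under which the truth is simulated.
#' @return A data.frame with columns `year`, `amount_hkd`.
#' @export
synthetic_expenditure <- function(fixture, true_params = list(),
                                  noise_cv = 0, seed = 1,
                                  years = 2009:2016,
                                  policy = baseline_policy()) {
  stopifnot(inherits(fixture, "ehcv_fixture"))
  check_nonneg(noise_cv, "noise_cv")
  fx <- apply_free_params(fixture, true_params)
  out <- run_scenario(simulation_config(fx, policy, fixture$start_year,
                                        max(years)))
  a <- out$annual[out$annual$year %in% years, ]
  amount <- a$expenditure_hkd
  if (noise_cv > 0) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    sdlog <- sqrt(log1p(noise_cv^2))
    amount <- amount * exp(stats::rnorm(length(amount), 0, sdlog) -
                             sdlog^2 / 2)
  }
  data.frame(year = a$year, amount_hkd = amount)
}
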