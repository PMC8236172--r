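#' Willingness-to-join parameters
#'
#' Scheme participation is modelled as a logistic function of calendar
#' time, capturing the low uptake of the pilot years rising towards an
#' asymptote as the scheme matured.
#'
#' @param w_max Asymptotic participation fraction, in `[0, 1]`.
#' @param growth_rate Logistic growth rate, 1/year (>= 0).
#' @param midpoint_year Calendar year at which participation reaches
#'   `w_max / 2`.
#' @return An object of class `ehcv_uptake`.
#' @export
uptake_params <- function(w_max, growth_rate, midpoint_year) {
  check_fraction(w_max, "w_max")
  check_nonneg(growth_rate, "growth_rate")
  stopifnot(length(w_max) == 1L, length(growth_rate) == 1L,
            length(midpoint_year) == 1L, is.finite(midpoint_year))
  structure(list(w_max = as.numeric(w_max),
                 growth_rate = as.numeric(growth_rate),
                 midpoint_year = as.numeric(midpoint_year)),
            class = "ehcv_uptake")
}

#' Participation fraction in a year
#'
#' `w_max / (1 + exp(-growth_rate * (year - midpoint_year)))`.
#'
#' @param year Calendar year (vectorized).
#' @param params An [uptake_params()].
#' @return Participation fraction(s) in `(0, w_max)`.
#' @export
#' @examples
#' willingness_at(2016, uptake_params(0.8, 0.5, 2012))  # 0.8 / (1 + exp(-2))
willingness_at <- function(year, params) {
  stopifnot(inherits(params, "ehcv_uptake"))
  params$w_max / (1 + exp(-params$growth_rate * (year - params$midpoint_year)))
}

#' Scale expected voucher visits by participation
#'
#' @param expected An [expected_voucher_visits()] result.
#' @param willingness Participation fraction in `[0, 1]`.
#' @return An `ehcv_voucher_visits` with every category scaled.
#' @export
actual_voucher_visits <- function(expected, willingness) {
  stopifnot(inherits(expected, "ehcv_voucher_visits"))
  check_fraction(willingness, "willingness")
  expected$visits <- expected$visits * willingness
  expected$total <- expected$total * willingness
  expected
}

#' Annual voucher claim expenditure
#'
#' Total claims are visits times the inflated category price, summed over
#' categories; chronic add-on spending, when present, is added at the
#' chronic claim price.
#'
#' @param actual_visits Visits/year per category (named numeric vector over
#'   [service_categories()], or an `ehcv_voucher_visits` whose bands are
#'   summed).
#' @param mix An [service_mix()].
#' @param year Calendar year.
#' @param chronic_visits Optional chronic voucher visits/year.
#' @param chronic_price Claim price of those visits, HKD.
#' @return Expenditure, HKD/year.
#' @export
annual_expenditure <- function(actual_visits, mix, year, chronic_visits = 0,
                               chronic_price = 0) {
  if (inherits(actual_visits, "ehcv_voucher_visits")) {
    actual_visits <- colSums(actual_visits$visits)
  }
  actual_visits <- check_nonneg(
    as_band_vector(actual_visits, "actual_visits", EHCV_CATEGORIES),
    "actual_visits")
  stopifnot(inherits(mix, "ehcv_mix"))
  check_nonneg(chronic_visits, "chronic_visits")
  sum(actual_visits * mix_prices(mix, year)) + chronic_visits * chronic_price
}
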