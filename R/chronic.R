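#' Parameters of the designated chronic-condition voucher
#'
#' The chronic add-on voucher targets the eligible population living with
#' chronic disease. Its utilization pattern is a monotone piecewise-linear
#' curve mapping the annual voucher amount to visits/person/year, with flat
#' extrapolation beyond the last knot (saturation) and zero use at zero
#' amount.
#'
#' @param prevalence Fraction with chronic disease per band, in `[0, 1]`.
#' @param curve A data.frame with columns `amount` (HKD/year, increasing
#'   from 0) and `visits` (visits/person/year, non-decreasing, 0 at 0).
#' @param price Claim price of a chronic follow-up visit, HKD (> 0).
#' @return An object of class `ehcv_chronic`.
#' @export
chronic_params <- function(prevalence, curve, price) {
  prevalence <- check_fraction(as_band_vector(prevalence, "prevalence"),
                               "prevalence")
  stopifnot(is.data.frame(curve),
            all(c("amount", "visits") %in% names(curve)), nrow(curve) >= 2L)
  curve <- curve[order(curve$amount), c("amount", "visits")]
  check_nonneg(curve$amount, "curve$amount")
  check_nonneg(curve$visits, "curve$visits")
  if (curve$amount[1L] != 0 || curve$visits[1L] != 0) {
    stop("utilization curve must start at the knot (0, 0)", call. = FALSE)
  }
  if (is.unsorted(curve$visits)) {
    stop("utilization curve must be non-decreasing in amount", call. = FALSE)
  }
  if (anyDuplicated(curve$amount)) {
    stop("utilization curve knots must have distinct amounts", call. = FALSE)
  }
  stopifnot(length(price) == 1L, is.finite(price), price > 0)
  structure(list(prevalence = prevalence, curve = curve,
                 price = as.numeric(price)),
            class = "ehcv_chronic")
}

#' Eligible chronic population per band
#'
#' Band population times chronic prevalence for bands at or above the
#' eligibility age; zero for younger bands.
#'
#' @param state An [population_state()].
#' @param params An [chronic_params()].
#' @param eligibility_age Scheme eligibility age (60, 65 or 70).
#' @return Named numeric vector of persons per band.
#' @export
chronic_eligible <- function(state, params, eligibility_age) {
  stopifnot(inherits(state, "ehcv_population"),
            inherits(params, "ehcv_chronic"))
  gate <- as.numeric(EHCV_BAND_LOWER_AGE >= eligibility_age)
  state$counts * params$prevalence * gate
}

#' Chronic voucher utilization at an amount
#'
#' Piecewise-linear interpolation of the utilization curve, flat beyond the
#' last knot.
#'
#' @param amount Annual chronic voucher amount, HKD (>= 0).
#' @param curve Utilization curve (data.frame `amount`, `visits`) as in
#'   [chronic_params()], or an `ehcv_chronic`.
#' @return Visits/person/year.
#' @export
#' @examples
#' crv <- data.frame(amount = c(0, 2000, 4000), visits = c(0, 4, 5))
#' chronic_utilization(1000, crv)  # 2
#' chronic_utilization(6000, crv)  # 5, saturated
chronic_utilization <- function(amount, curve) {
  if (inherits(curve, "ehcv_chronic")) curve <- curve$curve
  stopifnot(is.data.frame(curve))
  if (is.unsorted(curve$visits[order(curve$amount)])) {
    stop("utilization curve must be non-decreasing in amount", call. = FALSE)
  }
  check_nonneg(amount, "amount")
  stats::approx(curve$amount, curve$visits, xout = amount, rule = 2,
                ties = "ordered")$y
}

#' Total chronic voucher visits per year
#'
#' Sums eligible persons times per-person utilization over bands, with the
#' per-person rate capped at `amount / price` so total chronic spending
#' never exceeds the dollars allocated to the eligible population.
#'
#' @param eligible Persons per band, e.g. from [chronic_eligible()].
#' @param amount Annual chronic voucher amount, HKD.
#' @param params An [chronic_params()].
#' @return Total visits/year (scalar).
#' @export
chronic_voucher_visits <- function(eligible, amount, params) {
  stopifnot(inherits(params, "ehcv_chronic"))
  eligible <- check_nonneg(as_band_vector(eligible, "eligible"), "eligible")
  check_nonneg(amount, "amount")
  u <- min(chronic_utilization(amount, params$curve), amount / params$price)
  sum(eligible) * u
}
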