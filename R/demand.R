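#' Voucher service mix: budget weights, prices and inflation
#'
#' Voucher dollars are allocated across the five service categories by
#' fixed budget-share weights and converted to visits at category claim
#' prices, which inflate geometrically to capture supplier-induced demand.
#'
#' @param weight Budget share per category (see [service_categories()]);
#'   non-negative, summing to 1.
#' @param base_price Claim price per visit in HKD at `reference_year`
#'   (> 0).
#' @param inflation_rate Annual price inflation per category (>= 0).
#' @param reference_year Calendar year of the base prices.
#' @return An object of class `ehcv_mix`.
#' @export
service_mix <- function(weight, base_price, inflation_rate = 0,
                        reference_year = 2009) {
  weight <- as_band_vector(weight, "weight", EHCV_CATEGORIES)
  check_nonneg(weight, "weight")
  if (abs(sum(weight) - 1) > 1e-9) {
    stop("'weight' must sum to 1", call. = FALSE)
  }
  base_price <- as_band_vector(base_price, "base_price", EHCV_CATEGORIES)
  check_finite(base_price, "base_price")
  if (any(base_price <= 0)) stop("'base_price' must be > 0", call. = FALSE)
  inflation_rate <- check_nonneg(
    as_band_vector(inflation_rate, "inflation_rate", EHCV_CATEGORIES),
    "inflation_rate")
  stopifnot(length(reference_year) == 1L, is.finite(reference_year))
  structure(list(weight = weight, base_price = base_price,
                 inflation_rate = inflation_rate,
                 reference_year = as.integer(reference_year)),
            class = "ehcv_mix")
}

#' Inflate a claim price to a target year
#'
#' Geometric growth `base_price * (1 + rate)^(target_year - reference_year)`
#' models supplier-induced price escalation.
#'
#' @param base_price Price at `reference_year` (vectorized).
#' @param reference_year Year the base price refers to.
#' @param target_year Year to inflate to (>= `reference_year`).
#' @param rate Annual inflation rate (>= 0).
#' @return Inflated price(s), HKD/visit.
#' @export
#' @examples
#' inflate_price(260, 2016, 2018, 0.03)  # 260 * 1.03^2
inflate_price <- function(base_price, reference_year, target_year, rate) {
  check_finite(base_price, "base_price")
  check_nonneg(rate, "rate")
  if (any(target_year < reference_year)) {
    stop("'target_year' must not precede 'reference_year'", call. = FALSE)
  }
  base_price * (1 + rate)^(target_year - reference_year)
}

# per-category prices of a mix at a given year
mix_prices <- function(mix, year) {
  inflate_price(mix$base_price, mix$reference_year, year, mix$inflation_rate)
}

#' Expected voucher visits from an entitlement
#'
#' Constant-budget-share demand: each eligible person's annual entitlement
#' is allocated across service categories by the mix weights and divided by
#' the category's inflated price, so voucher dollars are conserved exactly
#' (`sum(visits * price) == sum(eligible) * entitlement`).
#'
#' @param eligible_counts Named numeric vector of eligible persons per band
#'   (zero for non-eligible bands).
#' @param entitlement Effective entitlement, HKD/person/year (>= 0).
#' @param mix An [service_mix()].
#' @param year Calendar year (drives price inflation).
#' @return An object of class `ehcv_voucher_visits`: `visits` is a
#'   band-by-category matrix of visits/year, `total` their sum.
#' @export
expected_voucher_visits <- function(eligible_counts, entitlement, mix, year) {
  eligible_counts <- check_nonneg(
    as_band_vector(eligible_counts, "eligible_counts"), "eligible_counts")
  check_nonneg(entitlement, "entitlement")
  stopifnot(inherits(mix, "ehcv_mix"))
  prices <- mix_prices(mix, year)
  if (any(!is.finite(prices) | prices <= 0)) {
    stop("inflated prices must be positive and finite", call. = FALSE)
  }
  visits <- outer(eligible_counts, entitlement * mix$weight / prices)
  dimnames(visits) <- list(EHCV_BANDS, EHCV_CATEGORIES)
  structure(list(visits = visits, total = sum(visits), year = year),
            class = "ehcv_voucher_visits")
}
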