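#' Assemble a model input bundle
#'
#' A fixture bundle collects every input the simulation engine needs:
#' the initial population, annual demographic/utilization rate tables
#' (piecewise-constant per calendar year), the voucher service mix, uptake,
#' substitution and chronic-voucher parameters, and an observed annual
#' claim-expenditure series for calibration. Every top-level field carries
#' a provenance tag (`anchored`, `assumed` or `synthetic`).
#'
#' @param start_year First simulated calendar year.
#' @param initial_population Named band counts at `start_year`.
#' @param demography A list with `years` (sorted calendar years) and
#'   annual-unit tables `birth_inflow` (persons/year), `death_rate`,
#'   `aging_rate` (fraction/year per band), `visit_rate`
#'   (visits/person/year per band) and `public_share` (fraction per band);
#'   each band table is a list of vectors along `years`.
#' @param mix An [service_mix()].
#' @param uptake An [uptake_params()].
#' @param substitution An [substitution_params()] for general voucher
#'   visits.
#' @param chronic An [chronic_params()].
#' @param chronic_substitution An [substitution_params()] for chronic
#'   add-on visits (chronic patients lean much more on the public sector,
#'   so their shift fraction is parameterized separately).
#' @param carry_release Fraction of the carry-forward balance drawn down
#'   per year on top of the annual allocation.
#' @param observed_expenditure Optional data.frame (`year`, `amount_hkd`)
#'   of annual voucher claims used by the calibration module.
#' @param provenance Named character vector tagging fields as `anchored`,
#'   `assumed` or `synthetic`.
#' @param meta Optional list of free-form metadata (name, description).
#' @return A validated object of class `ehcv_fixture`.
#' @export
fixture_bundle <- function(start_year, initial_population, demography, mix,
                           uptake, substitution, chronic,
                           chronic_substitution = substitution,
                           carry_release = 0.5,
                           observed_expenditure = NULL,
                           provenance = character(), meta = list()) {
  fx <- structure(list(
    start_year = as.integer(start_year),
    initial_population = as_band_vector(initial_population,
                                        "initial_population"),
    demography = demography,
    mix = mix,
    uptake = uptake,
    substitution = substitution,
    chronic = chronic,
    chronic_substitution = chronic_substitution,
    carry_release = as.numeric(carry_release),
    observed_expenditure = observed_expenditure,
    provenance = provenance,
    meta = meta), class = "ehcv_fixture")
  validate_fixture(fx)
}

#' Validate a fixture bundle
#'
#' Re-checks every component invariant (non-negative stocks and rates,
#' shares and fractions in range, monotone utilization curve, weights
#' summing to one, sorted year grids) and returns the fixture invisibly.
#'
#' @param fixture An `ehcv_fixture`.
#' @return The fixture, invisibly; errors describe the violated invariant.
#' @export
validate_fixture <- function(fixture) {
  stopifnot(inherits(fixture, "ehcv_fixture"))
  check_nonneg(fixture$initial_population, "initial_population")
  dem <- fixture$demography
  stopifnot(is.list(dem), !is.null(dem$years))
  years <- dem$years
  if (is.unsorted(years, strictly = TRUE)) {
    stop("demography$years must be strictly increasing", call. = FALSE)
  }
  n <- length(years)
  check_nonneg(dem$birth_inflow, "birth_inflow")
  stopifnot(length(dem$birth_inflow) == n)
  for (field in c("death_rate", "aging_rate", "visit_rate", "public_share")) {
    tab <- dem[[field]]
    stopifnot(is.list(tab), setequal(names(tab), EHCV_BANDS))
    for (b in EHCV_BANDS) {
      v <- tab[[b]]
      if (length(v) != n) {
        stop(sprintf("demography$%s$%s must have one value per year", field,
                     b), call. = FALSE)
      }
      if (field == "public_share") check_fraction(v, field)
      else check_nonneg(v, field)
    }
    if (field == "aging_rate" && any(tab$b70plus != 0)) {
      stop("aging_rate of b70plus must be 0", call. = FALSE)
    }
  }
  stopifnot(inherits(fixture$mix, "ehcv_mix"),
            inherits(fixture$uptake, "ehcv_uptake"),
            inherits(fixture$substitution, "ehcv_substitution"),
            inherits(fixture$chronic_substitution, "ehcv_substitution"),
            inherits(fixture$chronic, "ehcv_chronic"))
  if (fixture$mix$reference_year > fixture$start_year) {
    stop("mix reference_year must not follow the simulation start",
         call. = FALSE)
  }
  check_fraction(fixture$carry_release, "carry_release")
  obs <- fixture$observed_expenditure
  if (!is.null(obs)) {
    stopifnot(is.data.frame(obs),
              all(c("year", "amount_hkd") %in% names(obs)))
    if (is.unsorted(obs$year, strictly = TRUE)) {
      stop("observed_expenditure years must be strictly increasing",
           call. = FALSE)
    }
    check_nonneg(obs$amount_hkd, "observed_expenditure$amount_hkd")
  }
  invisible(fixture)
}

# weekly-rate lookup for a calendar year (piecewise-constant; years before
# the first table year use the first row)
rates_for_year <- function(fixture, year) {
  dem <- fixture$demography
  i <- max(findInterval(year, dem$years), 1L)
  pick <- function(tab) vapply(EHCV_BANDS, function(b) tab[[b]][i], numeric(1))
  demography_rates(
    birth_inflow = dem$birth_inflow[i] / 52,
    death_rate = pick(dem$death_rate) / 52,
    aging_rate = pick(dem$aging_rate) / 52,
    visit_rate = pick(dem$visit_rate) / 52,
    public_share = pick(dem$public_share))
}

#' Write a fixture bundle to JSON
#'
#' @param fixture An `ehcv_fixture`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_json <- function(fixture, path) {
  validate_fixture(fixture)
  x <- rapply(unclass(fixture), function(v) v, how = "replace")
  x$mix <- unclass(fixture$mix)
  x$uptake <- unclass(fixture$uptake)
  x$substitution <- unclass(fixture$substitution)
  x$chronic_substitution <- unclass(fixture$chronic_substitution)
  x$chronic <- list(prevalence = fixture$chronic$prevalence,
                    curve = fixture$chronic$curve,
                    price = fixture$chronic$price)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a fixture bundle from JSON
#'
#' @param path Path to a JSON file written by [write_fixture_json()].
#' @return A validated `ehcv_fixture`.
#' @export
read_fixture_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  obs <- x$observed_expenditure
  if (!is.null(obs)) obs <- as.data.frame(obs)
  fixture_bundle(
    start_year = x$start_year,
    initial_population = unlist(x$initial_population),
    demography = x$demography,
    mix = service_mix(unlist(x$mix$weight), unlist(x$mix$base_price),
                      unlist(x$mix$inflation_rate), x$mix$reference_year),
    uptake = uptake_params(x$uptake$w_max, x$uptake$growth_rate,
                           x$uptake$midpoint_year),
    substitution = substitution_params(x$substitution$from_public,
                                       x$substitution$from_private,
                                       x$substitution$induced),
    chronic = chronic_params(unlist(x$chronic$prevalence),
                             as.data.frame(x$chronic$curve),
                             x$chronic$price),
    chronic_substitution = substitution_params(
      x$chronic_substitution$from_public,
      x$chronic_substitution$from_private,
      x$chronic_substitution$induced),
    carry_release = x$carry_release,
    observed_expenditure = obs,
    provenance = unlist(x$provenance),
    meta = x$meta)
}

#' Read or write an annual expenditure series as CSV
#'
#' Two columns: `year` and `amount_hkd`.
#'
#' @param path CSV file path.
#' @return `read_expenditure_csv()` returns a data.frame;
#'   `write_expenditure_csv()` returns `path` invisibly.
#' @export
read_expenditure_csv <- function(path) {
  x <- utils::read.csv(path)
  stopifnot(all(c("year", "amount_hkd") %in% names(x)))
  x <- x[order(x$year), c("year", "amount_hkd")]
  check_nonneg(x$amount_hkd, "amount_hkd")
  x
}

#' @rdname read_expenditure_csv
#' @param series Data.frame with columns `year`, `amount_hkd`.
#' @export
write_expenditure_csv <- function(series, path) {
  stopifnot(all(c("year", "amount_hkd") %in% names(series)))
  utils::write.csv(series[, c("year", "amount_hkd")], path,
                   row.names = FALSE)
  invisible(path)
}
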