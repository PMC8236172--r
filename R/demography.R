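#' Population state at a simulation time point
#'
#' A stock vector of persons per age band together with the week index
#' (weeks since simulation start).
#'
#' @param counts Named numeric vector of persons per band (see
#'   [age_bands()]); all entries must be non-negative.
#' @param week_index Weeks since simulation start (>= 0; fractional values
#'   arise with sub-weekly Euler steps).
#' @return An object of class `ehcv_population`.
#' @seealso [step_population()], [generate_visits()]
#' @export
#' @examples
#' population_state(c(under60 = 5.9e6, b60_64 = 3.4e5,
#'                    b65_69 = 2.6e5, b70plus = 6.2e5))
population_state <- function(counts, week_index = 0) {
  counts <- as_band_vector(counts, "counts")
  check_nonneg(counts, "counts")
  if (!is.numeric(week_index) || length(week_index) != 1L ||
      !is.finite(week_index) || week_index < 0) {
    stop("'week_index' must be a single non-negative number", call. = FALSE)
  }
  structure(list(counts = counts, week_index = as.numeric(week_index)),
            class = "ehcv_population")
}

#' Weekly demographic and utilization rates
#'
#' All rates are per week. Annual tables in a fixture are converted by
#' simple division by 52, consistent with linear Euler flows on a 52-week
#' year.
#'
#' @param birth_inflow Persons/week entering the under-60 band.
#' @param death_rate Fraction/week dying, per band.
#' @param aging_rate Fraction/week moving to the next older band, per band;
#'   must be 0 for the terminal 70+ band. For the five-year bands the
#'   conventional first-order value is `1 / (5 * 52)`.
#' @param visit_rate Primary-care visits/person/week, per band.
#' @param public_share Baseline fraction of visits made in the public
#'   sector, per band, in `[0, 1]`; assumed independent of voucher use.
#' @return An object of class `ehcv_rates`.
#' @export
demography_rates <- function(birth_inflow = 0, death_rate = 0, aging_rate = 0,
                             visit_rate = 0, public_share = 0) {
  check_nonneg(birth_inflow, "birth_inflow")
  stopifnot(length(birth_inflow) == 1L)
  death_rate <- check_nonneg(as_band_vector(death_rate, "death_rate"),
                             "death_rate")
  aging_rate <- check_nonneg(as_band_vector(aging_rate, "aging_rate"),
                             "aging_rate")
  if (aging_rate[["b70plus"]] != 0) {
    stop("'aging_rate' of the terminal band b70plus must be 0", call. = FALSE)
  }
  visit_rate <- check_nonneg(as_band_vector(visit_rate, "visit_rate"),
                             "visit_rate")
  public_share <- check_fraction(as_band_vector(public_share, "public_share"),
                                 "public_share")
  structure(list(birth_inflow = as.numeric(birth_inflow),
                 death_rate = death_rate, aging_rate = aging_rate,
                 visit_rate = visit_rate, public_share = public_share),
            class = "ehcv_rates")
}

#' Advance the population one Euler step
#'
#' Explicit Euler update of the age-band stocks: births enter the under-60
#' band, deaths remove a band-specific fraction, and aging transfers a
#' first-order outflow to the next older band. A step that would drive any
#' stock negative is an integration instability and raises an error (counts
#' are never clamped).
#'
#' @param state An [population_state()].
#' @param rates An [demography_rates()] in weekly units.
#' @param dt Step size in weeks (> 0); `death_rate * dt` must stay below 1.
#' @return The advanced `ehcv_population`.
#' @export
#' @examples
#' st <- population_state(c(under60 = 1e4, b60_64 = 0, b65_69 = 0, b70plus = 0))
#' rt <- demography_rates(death_rate = c(0.001, 0, 0, 0))
#' step_population(st, rt)$counts[["under60"]]  # 10000 * 0.999
step_population <- function(state, rates, dt = 1) {
  stopifnot(inherits(state, "ehcv_population"), inherits(rates, "ehcv_rates"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("'dt' must be a single positive number of weeks", call. = FALSE)
  }
  if (any(rates$death_rate * dt >= 1)) {
    stop("'death_rate * dt' must be < 1 for a stable Euler step",
         call. = FALSE)
  }
  counts <- step_counts(state$counts, rates, dt)
  bad <- counts < 0
  if (any(bad)) {
    stop(sprintf("Euler step drove band(s) %s negative; reduce dt or rates",
                 paste(EHCV_BANDS[bad], collapse = ", ")), call. = FALSE)
  }
  population_state(counts, state$week_index + dt)
}

# bare Euler update on the counts vector; no validation (engine inner loop)
step_counts <- function(counts, rates, dt) {
  aging_out <- rates$aging_rate * counts
  inflow <- c(rates$birth_inflow, aging_out[1L], aging_out[2L], aging_out[3L])
  counts + dt * (inflow - rates$death_rate * counts - aging_out)
}

#' Generate weekly visit flows from the population
#'
#' Total visits per band are the product of band population and the average
#' per-person visit rate. Use [split_public_private()] to divide the totals
#' into baseline public and private streams.
#'
#' @inheritParams step_population
#' @return An object of class `ehcv_visits` with element `total`
#'   (visits/week per band); `public_base`/`private_base` are `NULL` until
#'   the flows are split.
#' @export
generate_visits <- function(state, rates) {
  stopifnot(inherits(state, "ehcv_population"), inherits(rates, "ehcv_rates"))
  structure(list(total = state$counts * rates$visit_rate,
                 public_base = NULL, private_base = NULL),
            class = "ehcv_visits")
}

#' Split visit flows into baseline public and private streams
#'
#' Applies the baseline public share per band, which the model treats as
#' independent of voucher use; the private stream is the complement.
#'
#' @param flows An `ehcv_visits` object from [generate_visits()].
#' @param rates An [demography_rates()] carrying `public_share`.
#' @return The completed `ehcv_visits` with `public_base + private_base ==
#'   total` per band.
#' @export
split_public_private <- function(flows, rates) {
  stopifnot(inherits(flows, "ehcv_visits"), inherits(rates, "ehcv_rates"))
  check_fraction(rates$public_share, "public_share")
  flows$public_base <- rates$public_share * flows$total
  flows$private_base <- flows$total - flows$public_base
  flows
}

#' @export
print.ehcv_population <- function(x, ...) {
  cat(sprintf("<ehcv_population> week %g\n", x$week_index))
  print(round(x$counts))
  invisible(x)
}
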