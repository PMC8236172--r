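#' A voucher policy epoch
#'
#' One span of scheme rules starting at a calendar year: the annual voucher
#' amount, the age-eligibility threshold, and the carry-forward cap on the
#' accumulated balance (0 disables carry-forward).
#'
#' @param start_year First calendar year the epoch is in force.
#' @param annual_amount Voucher allocation, HKD/person/year (>= 0).
#' @param eligibility_age One of 60, 65, 70.
#' @param carry_cap Carry-forward cap in HKD; must be 0 or at least
#'   `annual_amount`.
#' @return An object of class `ehcv_epoch`.
#' @export
policy_epoch <- function(start_year, annual_amount, eligibility_age = 70,
                         carry_cap = 0) {
  stopifnot(length(start_year) == 1L, is.finite(start_year))
  check_nonneg(annual_amount, "annual_amount")
  if (!eligibility_age %in% c(60, 65, 70)) {
    stop("'eligibility_age' must be one of 60, 65, 70", call. = FALSE)
  }
  check_nonneg(carry_cap, "carry_cap")
  if (carry_cap != 0 && carry_cap < annual_amount) {
    stop("'carry_cap' must be 0 (no carry-forward) or >= 'annual_amount'",
         call. = FALSE)
  }
  structure(list(start_year = as.integer(start_year),
                 annual_amount = as.numeric(annual_amount),
                 eligibility_age = as.numeric(eligibility_age),
                 carry_cap = as.numeric(carry_cap)),
            class = "ehcv_epoch")
}

#' A time-varying voucher policy
#'
#' An ordered sequence of [policy_epoch()]s plus an optional designated
#' chronic-condition add-on voucher (an extra annual amount for the
#' eligible population with chronic disease, redeemable privately only).
#'
#' @param epochs A list of [policy_epoch()]s (or a single epoch); start
#'   years must be unique.
#' @param chronic_amount Chronic add-on, HKD/person/year (0 = none).
#' @param chronic_start_year First calendar year of the add-on; required
#'   when `chronic_amount > 0`.
#' @return An object of class `ehcv_policy`.
#' @seealso [baseline_policy()], [policy_at()], [apply_scenario()]
#' @export
voucher_policy <- function(epochs, chronic_amount = 0,
                           chronic_start_year = NA_integer_) {
  if (inherits(epochs, "ehcv_epoch")) epochs <- list(epochs)
  stopifnot(length(epochs) >= 1L,
            all(vapply(epochs, inherits, logical(1), "ehcv_epoch")))
  starts <- vapply(epochs, `[[`, integer(1), "start_year")
  if (anyDuplicated(starts)) {
    stop("epoch start years must be unique", call. = FALSE)
  }
  epochs <- epochs[order(starts)]
  check_nonneg(chronic_amount, "chronic_amount")
  if (chronic_amount > 0 && is.na(chronic_start_year)) {
    stop("'chronic_start_year' is required when 'chronic_amount' > 0",
         call. = FALSE)
  }
  structure(list(epochs = epochs,
                 chronic_amount = as.numeric(chronic_amount),
                 chronic_start_year = as.integer(chronic_start_year)),
            class = "ehcv_policy")
}

#' The historical EHCV baseline policy
#'
#' The scheme as implemented: $250/year for ages 70+ in 2009--2011, $500 in
#' 2012, $1000 in 2013, $2000 from 2014 with carry-forward capped at $4000,
#' and age eligibility lowered to 65 from 2017. The 2009 pilot's five $50
#' vouchers are modelled as their $250 annual total.
#'
#' @return An `ehcv_policy`.
#' @export
baseline_policy <- function() {
  voucher_policy(list(
    policy_epoch(2009, 250, 70, 0),
    policy_epoch(2012, 500, 70, 0),
    policy_epoch(2013, 1000, 70, 0),
    policy_epoch(2014, 2000, 70, 4000),
    policy_epoch(2017, 2000, 65, 4000)
  ))
}

# epoch in force before the scheme starts
null_epoch <- function() policy_epoch(-1L, 0, 70, 0)

#' Look up the policy epoch in force in a year
#'
#' Epochs are piecewise-constant and right-continuous in calendar year:
#' the epoch with the latest `start_year <= year` applies. Years before the
#' first epoch (pre-scheme) return a null epoch with amount 0.
#'
#' @param policy An [voucher_policy()].
#' @param year Calendar year.
#' @return The [policy_epoch()] in force.
#' @export
#' @examples
#' policy_at(baseline_policy(), 2013)$annual_amount  # 1000
#' policy_at(baseline_policy(), 2008)$annual_amount  # 0, scheme not started
policy_at <- function(policy, year) {
  stopifnot(inherits(policy, "ehcv_policy"), length(year) == 1L,
            is.finite(year))
  starts <- vapply(policy$epochs, `[[`, integer(1), "start_year")
  i <- findInterval(year, starts)
  if (i == 0L) return(null_epoch())
  policy$epochs[[i]]
}

#' Carry an unspent voucher balance forward
#'
#' The new available balance is the unspent balance plus the new annual
#' allocation, truncated at the cap; with no carry-forward (cap 0) only the
#' new allocation is available.
#'
#' @param unspent Unspent balance, HKD/person (>= 0).
#' @param new_allocation New annual allocation, HKD/person (>= 0).
#' @param cap Carry-forward cap in HKD; 0 disables carry-forward.
#' @return Available balance, HKD/person.
#' @export
#' @examples
#' carry_forward(3000, 2000, 4000)  # capped at 4000
carry_forward <- function(unspent, new_allocation, cap) {
  check_nonneg(unspent, "unspent")
  check_nonneg(new_allocation, "new_allocation")
  check_nonneg(cap, "cap")
  ifelse(cap > 0, pmin(unspent + new_allocation, cap), new_allocation)
}

#' A named scenario: dated overrides of a baseline policy
#'
#' @param name Scenario name.
#' @param events A data.frame with columns `year`, `attribute`, `value`;
#'   attributes limited to `annual_amount`, `eligibility_age`,
#'   `chronic_amount`. An empty event table is the identity scenario.
#' @return An object of class `ehcv_scenario`.
#' @export
scenario_spec <- function(name, events = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(events)) {
    events <- data.frame(year = integer(), attribute = character(),
                         value = numeric())
  }
  stopifnot(is.data.frame(events),
            all(c("year", "attribute", "value") %in% names(events)))
  ok <- c("annual_amount", "eligibility_age", "chronic_amount")
  bad <- setdiff(events$attribute, ok)
  if (length(bad)) {
    stop(sprintf("unknown scenario attribute(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(events$year < 2009)) {
    stop("scenario events cannot predate the 2009 scheme start",
         call. = FALSE)
  }
  structure(list(name = name,
                 events = events[order(events$year), , drop = FALSE]),
            class = "ehcv_scenario")
}

#' Apply a scenario to a baseline policy
#'
#' Each event inserts (or replaces) an epoch at its year, copying the
#' epoch previously in force and overriding one attribute; `chronic_amount`
#' events switch on the chronic add-on from the event year. The baseline
#' object is not modified, and applying the same event list twice yields
#' the same policy (idempotence).
#'
#' When an amount override exceeds the epoch's carry cap, the cap is raised
#' to the new amount so the cap invariant (cap >= amount or 0) holds.
#'
#' @param baseline An [voucher_policy()].
#' @param scenario An [scenario_spec()].
#' @return A new `ehcv_policy`.
#' @export
apply_scenario <- function(baseline, scenario) {
  stopifnot(inherits(baseline, "ehcv_policy"),
            inherits(scenario, "ehcv_scenario"))
  policy <- baseline
  ev <- scenario$events
  for (k in seq_len(nrow(ev))) {
    year <- ev$year[k]
    attr <- ev$attribute[k]
    value <- ev$value[k]
    if (attr == "chronic_amount") {
      policy$chronic_amount <- as.numeric(value)
      policy$chronic_start_year <- as.integer(year)
      next
    }
    cur <- policy_at(policy, year)
    fields <- list(annual_amount = cur$annual_amount,
                   eligibility_age = cur$eligibility_age,
                   carry_cap = cur$carry_cap)
    fields[[attr]] <- value
    if (fields$carry_cap != 0 && fields$carry_cap < fields$annual_amount) {
      fields$carry_cap <- fields$annual_amount
    }
    epoch <- policy_epoch(year, fields$annual_amount, fields$eligibility_age,
                          fields$carry_cap)
    starts <- vapply(policy$epochs, `[[`, integer(1), "start_year")
    policy$epochs[starts == year] <- NULL
    policy$epochs <- c(policy$epochs, list(epoch))
    starts <- vapply(policy$epochs, `[[`, integer(1), "start_year")
    policy$epochs <- policy$epochs[order(starts)]
  }
  policy
}

#' Packaged policy scenarios
#'
#' The four tested strategies: `baseline` (no change); `amount_escalation`
#' ($3000, $4000, $5000 from 2021, 2025, 2029, keeping the historical pace
#' of roughly $1000 every four years); `age_lowering` (eligibility extended
#' to ages 60--64 from 2021); `chronic_voucher` (an extra $2000/year
#' designated for chronic-condition follow-up from 2021).
#'
#' @param name One of `"baseline"`, `"amount_escalation"`, `"age_lowering"`,
#'   `"chronic_voucher"`.
#' @return An [scenario_spec()].
#' @export
#' @examples
#' pol <- apply_scenario(baseline_policy(), ehcv_scenario("amount_escalation"))
#' policy_at(pol, 2025)$annual_amount  # 4000
ehcv_scenario <- function(name = c("baseline", "amount_escalation",
                                   "age_lowering", "chronic_voucher")) {
  name <- match.arg(name)
  events <- switch(name,
    baseline = NULL,
    amount_escalation = data.frame(
      year = c(2021L, 2025L, 2029L),
      attribute = "annual_amount",
      value = c(3000, 4000, 5000)),
    age_lowering = data.frame(
      year = 2021L, attribute = "eligibility_age", value = 60),
    chronic_voucher = data.frame(
      year = 2021L, attribute = "chronic_amount", value = 2000))
  scenario_spec(name, events)
}

#' @export
print.ehcv_policy <- function(x, ...) {
  cat("<ehcv_policy>\n")
  for (e in x$epochs) {
    cat(sprintf("  %d: $%g/yr, age %g+, cap $%g\n", e$start_year,
                e$annual_amount, e$eligibility_age, e$carry_cap))
  }
  if (x$chronic_amount > 0) {
    cat(sprintf("  chronic add-on: $%g/yr from %d\n", x$chronic_amount,
                x$chronic_start_year))
  }
  invisible(x)
}
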