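#' Configure a simulation run
#'
#' @param fixture An [fixture_bundle()].
#' @param scenario What to simulate: a packaged scenario name (see
#'   [ehcv_scenario()]), an [scenario_spec()] applied to the historical
#'   baseline, or an [voucher_policy()] used as-is.
#' @param start_year,end_year Simulated horizon (inclusive); defaults
#'   2009--2032.
#' @param dt Euler step in weeks; must divide the 52-week model year
#'   evenly.
#' @return An object of class `ehcv_config`.
#' @export
simulation_config <- function(fixture, scenario = "baseline",
                              start_year = 2009, end_year = 2032, dt = 1) {
  stopifnot(inherits(fixture, "ehcv_fixture"))
  if (is.character(scenario)) scenario <- ehcv_scenario(scenario)
  if (inherits(scenario, "ehcv_scenario")) {
    policy <- apply_scenario(baseline_policy(), scenario)
    scenario_name <- scenario$name
  } else if (inherits(scenario, "ehcv_policy")) {
    policy <- scenario
    scenario_name <- "custom_policy"
  } else {
    stop("'scenario' must be a name, an ehcv_scenario or an ehcv_policy",
         call. = FALSE)
  }
  stopifnot(start_year < end_year)
  steps <- 52 / dt
  if (!is.finite(steps) || abs(steps - round(steps)) > 1e-9) {
    stop("'dt' must divide the 52-week year evenly", call. = FALSE)
  }
  structure(list(fixture = fixture, policy = policy,
                 scenario_name = scenario_name,
                 start_year = as.integer(start_year),
                 end_year = as.integer(end_year), dt = as.numeric(dt)),
            class = "ehcv_config")
}

# per-year precomputed quantities shared by the weekly steps
year_context <- function(fixture, policy, year) {
  rates <- rates_for_year(fixture, year)
  epoch <- policy_at(policy, year)
  elig <- as.numeric(EHCV_BAND_LOWER_AGE >= epoch$eligibility_age)
  prices <- mix_prices(fixture$mix, max(year, fixture$mix$reference_year))
  chronic_on <- policy$chronic_amount > 0 &&
    !is.na(policy$chronic_start_year) && year >= policy$chronic_start_year
  # chronic claims face the same supplier-induced inflation as the general
  # chronic follow-up category; the fixture price is quoted at the mix
  # reference year
  chronic_price <- inflate_price(
    fixture$chronic$price, fixture$mix$reference_year,
    max(year, fixture$mix$reference_year),
    fixture$mix$inflation_rate[["chronic_follow_up"]])
  u_chronic <- if (chronic_on) {
    min(chronic_utilization(policy$chronic_amount, fixture$chronic$curve),
        policy$chronic_amount / chronic_price)
  } else 0
  list(rates = rates, epoch = epoch, elig = elig,
       willingness = willingness_at(year, fixture$uptake),
       prices = prices, weight = fixture$mix$weight,
       chronic_on = chronic_on, u_chronic = u_chronic,
       chronic_price = chronic_price)
}

# flows over one Euler step of length dt weeks; counts taken at step start.
# entitle: HKD/person/year per band. Returns visit and dollar flows (per
# step, i.e. already scaled by dt/52 where annual).
step_flows <- function(counts, ctx, entitle, fixture, dt) {
  total <- counts * ctx$rates$visit_rate * dt
  public_base <- ctx$rates$public_share * total
  private_base <- total - public_base
  dollars <- sum(counts * ctx$elig * entitle) * ctx$willingness * dt / 52
  voucher_cat <- dollars * ctx$weight / ctx$prices
  v_gen <- sum(voucher_cat)
  v_chronic <- if (ctx$chronic_on) {
    ctx$willingness * sum(counts * fixture$chronic$prevalence * ctx$elig) *
      ctx$u_chronic * dt / 52
  } else 0

  pub <- sum(public_base)
  priv <- sum(private_base)
  sg <- fixture$substitution
  sc <- fixture$chronic_substitution
  shift_g <- min(sg$from_public * v_gen, pub)
  shift_c <- min(sc$from_public * v_chronic, pub - shift_g)
  truncated <- shift_g < sg$from_public * v_gen ||
    shift_c < sc$from_public * v_chronic
  public <- pub - shift_g - shift_c
  private <- priv + shift_g + sg$induced * v_gen +
    shift_c + sc$induced * v_chronic

  list(total = total, public_base = public_base, private_base = private_base,
       voucher_cat = voucher_cat, v_chronic = v_chronic,
       public = public, private = private,
       expenditure = dollars + v_chronic * ctx$chronic_price,
       truncated = truncated)
}

#' Advance the full model one Euler step
#'
#' One week (or `dt` weeks) of the wired model: demographic step, visit
#' generation and public/private split, voucher demand under the policy
#' epoch in force, willingness scaling, chronic add-on, sector shift and
#' expenditure accrual. [run_scenario()] composes this step over the whole
#' horizon; it is exposed for inspection and step-size experiments.
#'
#' @param state An [population_state()].
#' @param fixture An [fixture_bundle()].
#' @param policy An [voucher_policy()].
#' @param week Week index since `fixture$start_year` (week 0 = first week).
#' @param dt Step length in weeks.
#' @param carry Carry-forward balance per band, HKD/person.
#' @return A list with the advanced `state` and the step's `flows`
#'   (visits by band, sector totals after shift, voucher visits by
#'   category, chronic visits, expenditure).
#' @export
integrate_week <- function(state, fixture, policy, week, dt = 1, carry = 0) {
  stopifnot(inherits(state, "ehcv_population"),
            inherits(fixture, "ehcv_fixture"),
            inherits(policy, "ehcv_policy"))
  carry <- check_nonneg(as_band_vector(carry, "carry"), "carry")
  year <- fixture$start_year + floor(week / 52)
  ctx <- year_context(fixture, policy, year)
  avail <- ctx$elig *
    carry_forward(carry, ctx$epoch$annual_amount, ctx$epoch$carry_cap)
  entitle <- pmin(ctx$epoch$annual_amount + fixture$carry_release * carry,
                  avail) * ctx$elig
  flows <- step_flows(state$counts, ctx, entitle, fixture, dt)
  list(state = step_population(state, ctx$rates, dt), flows = flows)
}

#' Run a policy scenario over the simulation horizon
#'
#' Integrates the full stock-and-flow model with weekly Euler steps over a
#' 52-week model year and aggregates flows to calendar years. Runs are
#' deterministic: identical configurations produce identical output.
#'
#' @param config An [simulation_config()].
#' @return An object of class `ehcv_output`; element `annual` is a
#'   data.frame with one row per simulated year: end-of-year population and
#'   annual visit totals per band, public/private visits after the voucher
#'   shift, their ratio (`NA` when private visits are zero), voucher visits
#'   per service category, chronic voucher visits, and claim expenditure in
#'   HKD.
#' @export
#' @examples
#' \donttest{
#' out <- run_scenario(simulation_config(hk_anchor_fixture()))
#' subset(out$annual, year %in% c(2018, 2032),
#'        c(year, visits_public, visits_private, ratio_public_private))
#' }
run_scenario <- function(config) {
  stopifnot(inherits(config, "ehcv_config"))
  fixture <- config$fixture
  policy <- config$policy
  years <- config$start_year:config$end_year
  steps_per_year <- as.integer(round(52 / config$dt))
  dt <- config$dt

  counts <- as_band_vector(fixture$initial_population, "initial_population")
  carry <- stats::setNames(numeric(4L), EHCV_BANDS)
  rows <- vector("list", length(years))

  for (yi in seq_along(years)) {
    year <- years[yi]
    ctx <- year_context(fixture, policy, year)
    avail <- ctx$elig *
      carry_forward(carry, ctx$epoch$annual_amount, ctx$epoch$carry_cap)
    entitle <- pmin(ctx$epoch$annual_amount + fixture$carry_release * carry,
                    avail) * ctx$elig

    acc_visits <- stats::setNames(numeric(4L), EHCV_BANDS)
    acc_cat <- stats::setNames(numeric(5L), EHCV_CATEGORIES)
    acc <- c(public = 0, private = 0, chronic = 0, expenditure = 0)
    truncated <- FALSE

    for (s in seq_len(steps_per_year)) {
      fl <- step_flows(counts, ctx, entitle, fixture, dt)
      acc_visits <- acc_visits + fl$total
      acc_cat <- acc_cat + fl$voucher_cat
      acc["public"] <- acc["public"] + fl$public
      acc["private"] <- acc["private"] + fl$private
      acc["chronic"] <- acc["chronic"] + fl$v_chronic
      acc["expenditure"] <- acc["expenditure"] + fl$expenditure
      truncated <- truncated || fl$truncated
      counts <- step_counts(counts, ctx$rates, dt)
      if (any(counts < 0)) {
        stop(sprintf(
          "integration instability: band(s) %s negative in year %d, step %d",
          paste(EHCV_BANDS[counts < 0], collapse = ", "), year, s),
          call. = FALSE)
      }
    }
    if (truncated) {
      warning(sprintf(
        "year %d: public-to-private shift truncated at the public baseline",
        year), call. = FALSE)
    }
    spend <- ctx$willingness * entitle
    carry <- pmax(avail - spend, 0) * ctx$elig

    rows[[yi]] <- data.frame(
      year = year,
      pop_under60 = counts[["under60"]], pop_60_64 = counts[["b60_64"]],
      pop_65_69 = counts[["b65_69"]], pop_70plus = counts[["b70plus"]],
      visits_under60 = acc_visits[["under60"]],
      visits_60_64 = acc_visits[["b60_64"]],
      visits_65_69 = acc_visits[["b65_69"]],
      visits_70plus = acc_visits[["b70plus"]],
      visits_total = sum(acc_visits),
      visits_public = acc[["public"]], visits_private = acc[["private"]],
      ratio_public_private =
        if (acc[["private"]] > 0) acc[["public"]] / acc[["private"]]
        else NA_real_,
      voucher_visits_non_preventive = acc_cat[["non_preventive"]],
      voucher_visits_chronic_follow_up = acc_cat[["chronic_follow_up"]],
      voucher_visits_dentistry = acc_cat[["dentistry"]],
      voucher_visits_vaccination = acc_cat[["vaccination"]],
      voucher_visits_other = acc_cat[["other"]],
      chronic_voucher_visits = acc[["chronic"]],
      expenditure_hkd = acc[["expenditure"]])
  }
  annual <- do.call(rbind, rows)
  rownames(annual) <- NULL
  echo <- config[c("start_year", "end_year", "dt", "scenario_name")]
  echo$fixture_provenance <- fixture$provenance
  structure(list(annual = annual, scenario = config$scenario_name,
                 config = echo),
            class = "ehcv_output")
}

#' Compare scenario runs against a baseline
#'
#' Runs each configuration and reports, per year and scenario, the change
#' in public visits, private visits and the public-to-private ratio
#' relative to the first configuration. All configurations must share the
#' fixture, horizon and step size.
#'
#' @param configs A list of [simulation_config()]s; the first is the
#'   reference.
#' @return A data.frame with columns `year`, `scenario`, `d_public_visits`,
#'   `d_private_visits`, `d_ratio`.
#' @export
compare_scenarios <- function(configs) {
  stopifnot(is.list(configs), length(configs) >= 1L,
            all(vapply(configs, inherits, logical(1), "ehcv_config")))
  ref <- configs[[1L]]
  for (cf in configs[-1L]) {
    if (cf$start_year != ref$start_year || cf$end_year != ref$end_year ||
        cf$dt != ref$dt) {
      stop("all configurations must share the simulation horizon and dt",
           call. = FALSE)
    }
    if (!identical(cf$fixture, ref$fixture)) {
      stop("all configurations must share the fixture", call. = FALSE)
    }
  }
  outs <- lapply(configs, run_scenario)
  base <- outs[[1L]]$annual
  do.call(rbind, lapply(outs, function(o) {
    a <- o$annual
    data.frame(year = a$year, scenario = o$scenario,
               d_public_visits = a$visits_public - base$visits_public,
               d_private_visits = a$visits_private - base$visits_private,
               d_ratio = a$ratio_public_private -
                 base$ratio_public_private)
  }))
}

#' @export
print.ehcv_output <- function(x, ...) {
  cat(sprintf("<ehcv_output> scenario '%s', %d-%d\n", x$scenario,
              x$config$start_year, x$config$end_year))
  cols <- c("year", "visits_public", "visits_private",
            "ratio_public_private", "expenditure_hkd")
  print(utils::head(x$annual[, cols]), row.names = FALSE)
  if (nrow(x$annual) > 6) cat(sprintf("... %d more years\n",
                                      nrow(x$annual) - 6L))
  invisible(x)
}
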