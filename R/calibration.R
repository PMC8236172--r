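#' Mean absolute percentage error between expenditure series
#'
#' `mean(|sim - obs| / obs) * 100` over the common (identical) year set.
#' The study's calibration fitness bound keeps MAPE below 40%.
#'
#' @param simulated,observed Data.frames with columns `year`,
#'   `amount_hkd`; identical non-empty year sets, observed amounts > 0.
#' @return MAPE in percent.
#' @export
#' @examples
#' obs <- data.frame(year = 1:3, amount_hkd = c(100, 200, 400))
#' sim <- data.frame(year = 1:3, amount_hkd = c(90, 220, 400))
#' mape(sim, obs)  # 6.67
mape <- function(simulated, observed) {
  m <- align_series(simulated, observed)
  if (any(m$obs == 0)) {
    stop("MAPE is undefined for observed values of 0", call. = FALSE)
  }
  mean(abs(m$sim - m$obs) / m$obs) * 100
}

#' Coefficient of determination between expenditure series
#'
#' `1 - SS_res / SS_tot` about the observed mean; can be negative for fits
#' worse than the mean.
#'
#' @inheritParams mape
#' @return R-squared (dimensionless, <= 1).
#' @export
r_squared <- function(simulated, observed) {
  m <- align_series(simulated, observed)
  ss_tot <- sum((m$obs - mean(m$obs))^2)
  if (ss_tot == 0) {
    stop("R-squared is undefined when the observed series is constant",
         call. = FALSE)
  }
  1 - sum((m$sim - m$obs)^2) / ss_tot
}

align_series <- function(simulated, observed) {
  stopifnot(is.data.frame(simulated), is.data.frame(observed),
            all(c("year", "amount_hkd") %in% names(simulated)),
            all(c("year", "amount_hkd") %in% names(observed)))
  if (nrow(observed) == 0L) stop("empty observed series", call. = FALSE)
  if (!setequal(simulated$year, observed$year)) {
    stop("simulated and observed series must cover the same years",
         call. = FALSE)
  }
  list(sim = simulated$amount_hkd[match(observed$year, simulated$year)],
       obs = observed$amount_hkd)
}

#' Override a calibratable fixture parameter
#'
#' Parameters are addressed by dotted path. Supported paths:
#' `uptake.w_max`, `uptake.growth_rate`, `uptake.midpoint_year`,
#' `carry_release`, `mix.inflation_rate` (sets all categories),
#' `substitution.from_public` / `chronic_substitution.from_public` (the
#' other two fractions are rescaled to keep the unit sum),
#' `chronic.scale` (multiplies the utilization curve),
#' `chronic.prevalence.scale`, `visit_rate.<band>.scale`,
#' `public_share.<band>` (constant over years),
#' `aging_rate.under60.scale`, `death_rate.<band>.scale`,
#' `birth_inflow.scale`.
#'
#' @param fixture An `ehcv_fixture`.
#' @param name Dotted parameter path.
#' @param value New value (scale factors multiply the packaged table).
#' @return The modified, re-validated fixture.
#' @export
set_fixture_param <- function(fixture, name, value) {
  stopifnot(inherits(fixture, "ehcv_fixture"), is.numeric(value),
            length(value) == 1L, is.finite(value))
  parts <- strsplit(name, ".", fixed = TRUE)[[1L]]
  head <- parts[1L]
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  if (head == "uptake" && length(parts) == 2L &&
      parts[2L] %in% c("w_max", "growth_rate", "midpoint_year")) {
    fixture$uptake[[parts[2L]]] <- value
    fixture$uptake <- do.call(uptake_params, unclass(fixture$uptake))
  } else if (head == "carry_release" && length(parts) == 1L) {
    fixture$carry_release <- value
  } else if (head == "mix" && identical(parts[2L], "inflation_rate")) {
    fixture$mix$inflation_rate[] <- value
    fixture$mix <- do.call(service_mix, unclass(fixture$mix))
  } else if (head %in% c("substitution", "chronic_substitution") &&
             identical(parts[2L], "from_public")) {
    s <- fixture[[head]]
    rest <- s$from_private + s$induced
    scale <- if (rest > 0) (1 - value) / rest else 0
    fixture[[head]] <- substitution_params(
      value, s$from_private * scale,
      1 - value - s$from_private * scale)
  } else if (head == "chronic" && identical(parts[2L], "scale") &&
             length(parts) == 2L) {
    fixture$chronic$curve$visits <- fixture$chronic$curve$visits * value
  } else if (head == "chronic" && identical(parts[2L], "prevalence")) {
    fixture$chronic$prevalence <- clamp01(fixture$chronic$prevalence * value)
  } else if (head %in% c("visit_rate", "death_rate") && length(parts) == 3L &&
             parts[2L] %in% EHCV_BANDS && parts[3L] == "scale") {
    fixture$demography[[head]][[parts[2L]]] <-
      fixture$demography[[head]][[parts[2L]]] * value
  } else if (head == "public_share" && length(parts) == 2L &&
             parts[2L] %in% EHCV_BANDS) {
    fixture$demography$public_share[[parts[2L]]][] <- clamp01(value)
  } else if (head == "aging_rate" && identical(parts[2L], "under60") &&
             identical(parts[3L], "scale")) {
    fixture$demography$aging_rate$under60 <-
      fixture$demography$aging_rate$under60 * value
  } else if (head == "birth_inflow" && identical(parts[2L], "scale")) {
    fixture$demography$birth_inflow <- fixture$demography$birth_inflow * value
  } else {
    stop(sprintf("unknown calibratable parameter '%s'", name), call. = FALSE)
  }
  validate_fixture(fixture)
}

#' Specify a calibration problem
#'
#' @param fixture The `ehcv_fixture` whose free parameters are fitted.
#' @param free Named list of `c(lower, upper)` bounds, one entry per free
#'   parameter path (see [set_fixture_param()]).
#' @param policy Policy simulated during fitting (default the historical
#'   baseline).
#' @param start_year,end_year Simulation horizon used for objective
#'   evaluation.
#' @param max_evaluations Cap on objective evaluations per local search.
#' @param n_starts Number of multi-start points (first start is the
#'   mid-bound point, the rest are drawn uniformly within bounds).
#' @param seed Integer seed making the multi-start draw reproducible.
#' @param anchor_weight Weight of the squared relative anchor errors added
#'   to the expenditure MAPE.
#' @return An object of class `ehcv_calspec`.
#' @export
calibration_spec <- function(fixture, free, policy = baseline_policy(),
                             start_year = fixture$start_year,
                             end_year = 2032, max_evaluations = 250,
                             n_starts = 3, seed = 1, anchor_weight = 100) {
  stopifnot(inherits(fixture, "ehcv_fixture"), is.list(free),
            length(free) >= 1L, !is.null(names(free)))
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1L] >= b[2L]) {
      stop(sprintf("bounds for '%s' must be finite and ordered", nm),
           call. = FALSE)
    }
    set_fixture_param(fixture, nm, mean(b))  # errors on unknown path now
  }
  structure(list(fixture = fixture, free = free, policy = policy,
                 start_year = start_year, end_year = end_year,
                 max_evaluations = as.integer(max_evaluations),
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 anchor_weight = as.numeric(anchor_weight)),
            class = "ehcv_calspec")
}

# pull an anchor quantity like "ratio_2018" or "public_visits_2032" from a run
extract_anchor <- function(annual, name) {
  m <- regmatches(name, regexec("^(.*)_([0-9]{4})$", name))[[1L]]
  if (length(m) != 3L) {
    stop(sprintf("anchor name '%s' must end in _<year>", name), call. = FALSE)
  }
  qty <- m[2L]
  row <- annual[annual$year == as.integer(m[3L]), , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("anchor year %s outside the simulated horizon", m[3L]),
         call. = FALSE)
  }
  switch(qty,
    ratio = row$ratio_public_private,
    public_visits = row$visits_public,
    private_visits = row$visits_private,
    total_visits = row$visits_total,
    share_b70plus = row$visits_70plus / row$visits_total,
    share_under60 = row$visits_under60 / row$visits_total,
    expenditure = row$expenditure_hkd,
    stop(sprintf("unknown anchor quantity '%s'", qty), call. = FALSE))
}

apply_free_params <- function(fixture, values) {
  for (nm in names(values)) {
    fixture <- set_fixture_param(fixture, nm, values[[nm]])
  }
  fixture
}

#' Fit free model parameters to observed expenditure (and anchors)
#'
#' Bounded derivative-free minimization of the expenditure MAPE plus
#' optional weighted squared relative anchor errors, by multi-start
#' Nelder--Mead local search on a logit-rescaled parameter space (a golden
#' -section search when a single parameter is free). The returned point is
#' always inside the bounds and its objective never exceeds that of any
#' start point; results are reproducible for a fixed seed.
#'
#' @param spec An [calibration_spec()].
#' @param observed Observed annual expenditure (`year`, `amount_hkd`),
#'   e.g. the Department of Health claim series or
#'   [synthetic_expenditure()]; may be `NULL` when fitting anchors only.
#' @param anchors Optional named targets, e.g.
#'   `list(ratio_2018 = 0.70, public_visits_2032 = 25.6e6)`; an entry may
#'   be `c(target, weight)` to up-weight an anchor (default weight 1).
#' @return An object of class `ehcv_calibration`: fitted parameter values,
#'   `mape` (percent), `r_squared`, `accepted` (`mape < 40`), the achieved
#'   objective, the start-point objectives, and the calibrated fixture.
#' @export
fit_parameters <- function(spec, observed = NULL, anchors = NULL) {
  stopifnot(inherits(spec, "ehcv_calspec"))
  if (is.null(observed) && is.null(anchors)) {
    stop("at least one of 'observed' and 'anchors' is required",
         call. = FALSE)
  }
  lower <- vapply(spec$free, `[`, numeric(1), 1L)
  upper <- vapply(spec$free, `[`, numeric(1), 2L)
  nms <- names(spec$free)
  npar <- length(nms)

  objective <- function(values) {
    fx <- apply_free_params(spec$fixture, stats::setNames(values, nms))
    out <- run_scenario(simulation_config(fx, spec$policy,
                                          spec$start_year, spec$end_year))
    obj <- 0
    if (!is.null(observed)) {
      sim <- data.frame(year = out$annual$year,
                        amount_hkd = out$annual$expenditure_hkd)
      sim <- sim[sim$year %in% observed$year, , drop = FALSE]
      obj <- obj + mape(sim, observed)
    }
    if (!is.null(anchors)) {
      err2 <- vapply(names(anchors), function(nm) {
        a <- anchors[[nm]]
        tgt <- a[1L]
        wt <- if (length(a) > 1L) a[2L] else 1
        wt * ((extract_anchor(out$annual, nm) - tgt) / tgt)^2
      }, numeric(1))
      obj <- obj + spec$anchor_weight * sum(err2)
    }
    if (!is.finite(obj)) obj <- 1e12
    obj
  }

  to_unit <- function(x) (x - lower) / (upper - lower)
  from_unit <- function(u) lower + pmin(pmax(u, 0), 1) * (upper - lower)

  if (npar == 1L) {
    opt <- stats::optimize(function(x) objective(x), lower = lower,
                           upper = upper, tol = (upper - lower) * 1e-4)
    best <- list(par = opt$minimum, value = opt$objective)
    start_objectives <- objective(mean(c(lower, upper)))
  } else {
    set.seed(spec$seed)
    starts <- rbind(rep(0.5, npar),
                    matrix(stats::runif((spec$n_starts - 1L) * npar),
                           ncol = npar))
    starts <- starts[seq_len(max(spec$n_starts, 1L)), , drop = FALSE]
    obj_z <- function(z) objective(from_unit(stats::plogis(z)))
    best <- NULL
    start_objectives <- numeric(nrow(starts))
    for (k in seq_len(nrow(starts))) {
      z0 <- stats::qlogis(pmin(pmax(starts[k, ], 0.02), 0.98))
      start_objectives[k] <- obj_z(z0)
      fit <- stats::optim(z0, obj_z, method = "Nelder-Mead",
                          control = list(maxit = spec$max_evaluations))
      cand <- list(par = from_unit(stats::plogis(fit$par)),
                   value = fit$value)
      if (start_objectives[k] < cand$value) {
        cand <- list(par = from_unit(stats::plogis(z0)),
                     value = start_objectives[k])
      }
      if (is.null(best) || cand$value < best$value) best <- cand
    }
  }
  if (all(is.finite(start_objectives)) &&
      !is.finite(best$value)) {
    stop("calibration failed: objective non-finite at every start",
         call. = FALSE)
  }
  fitted <- stats::setNames(as.numeric(best$par), nms)
  fx <- apply_free_params(spec$fixture, as.list(fitted))
  out <- run_scenario(simulation_config(fx, spec$policy, spec$start_year,
                                        spec$end_year))
  final_mape <- final_r2 <- NA_real_
  if (!is.null(observed)) {
    sim <- data.frame(year = out$annual$year,
                      amount_hkd = out$annual$expenditure_hkd)
    sim <- sim[sim$year %in% observed$year, , drop = FALSE]
    final_mape <- mape(sim, observed)
    final_r2 <- tryCatch(r_squared(sim, observed),
                         error = function(e) NA_real_)
  }
  structure(list(fitted = fitted, mape = final_mape, r_squared = final_r2,
                 accepted = isTRUE(final_mape < 40),
                 objective = best$value,
                 start_objectives = start_objectives,
                 fixture = fx),
            class = "ehcv_calibration")
}

#' @export
print.ehcv_calibration <- function(x, ...) {
  cat("<ehcv_calibration>\n  fitted:\n")
  for (nm in names(x$fitted)) {
    cat(sprintf("    %s = %.6g\n", nm, x$fitted[[nm]]))
  }
  cat(sprintf("  MAPE = %.2f%%, R^2 = %.4g, accepted = %s\n", x$mape,
              x$r_squared, x$accepted))
  invisible(x)
}
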