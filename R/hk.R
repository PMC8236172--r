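# cache so repeated loads skip re-reading and re-checking the packaged files
.ehcv_cache <- new.env(parent = emptyenv())

#' The packaged Hong Kong anchored fixture
#'
#' A reconstruction of the study inputs (Census-style age-structured
#' population, household-survey utilization proportions and shares, claim
#' prices, uptake and substitution behaviour) calibrated so that the
#' baseline and scenario runs reproduce the published trajectory values.
#' The underlying administrative data are not public, so every field is
#' tagged `anchored` (tuned against a printed value) or `assumed`
#' (plausible reconstruction); the observed expenditure series shipped
#' with the fixture is itself a synthetic reconstruction of the claims
#' trend. The fixture is regenerated by `scripts/build_hk_fixture.R`.
#'
#' @param check Run the anchor self-check on load (cached; an integrity
#'   error is raised if the packaged fixture misses an anchor tolerance).
#' @return A validated `ehcv_fixture`.
#' @seealso [check_hk_fixture()], [hk_anchor_targets()]
#' @export
hk_anchor_fixture <- function(check = TRUE) {
  if (is.null(.ehcv_cache$hk_fixture)) {
    path <- system.file("extdata", "hk_fixture.json", package = "ehcvsim",
                        mustWork = TRUE)
    fx <- read_fixture_json(path)
    obs <- system.file("extdata", "hk_observed_expenditure.csv",
                       package = "ehcvsim", mustWork = TRUE)
    fx$observed_expenditure <- read_expenditure_csv(obs)
    .ehcv_cache$hk_fixture <- validate_fixture(fx)
  }
  if (check && !isTRUE(.ehcv_cache$hk_checked)) {
    res <- check_hk_fixture(.ehcv_cache$hk_fixture)
    if (!all(res$pass)) {
      bad <- res[!res$pass, ]
      stop(sprintf(
        "packaged HK fixture failed its anchor self-check: %s",
        paste(sprintf("%s (achieved %.4g, target %.4g)", bad$name,
                      bad$achieved, bad$target), collapse = "; ")),
        call. = FALSE)
    }
    .ehcv_cache$hk_checked <- TRUE
  }
  .ehcv_cache$hk_fixture
}

#' Published trajectory anchors of the HK fixture
#'
#' The printed values the anchored fixture is calibrated against, with the
#' scenario each belongs to and its relative self-check tolerance. The
#' default tolerance is 10%; the 2019 private-visit level carries 20%
#' because the published sector levels and the published 2018
#' public-to-private ratio are mutually inconsistent (16.3M public and
#' 18.0M private visits imply a ratio near 0.9, not 0.70), so no single
#' parameterization can match both within 10% -- the fixture favours the
#' ratio and the public level.
#'
#' @return A data.frame with columns `name` (anchor quantity, see
#'   [set_fixture_param()] anchors), `scenario`, `target`, `tolerance`.
#' @export
hk_anchor_targets <- function() {
  data.frame(
    name = c("share_b70plus_2009", "share_under60_2009",
             "ratio_2018", "public_visits_2018",
             "public_visits_2019", "private_visits_2019",
             "ratio_2032", "public_visits_2032", "private_visits_2032",
             "share_b70plus_2032", "share_under60_2032",
             "d_public_2021", "ratio_2021",
             "d_public_2021", "ratio_2021"),
    scenario = c(rep("baseline", 11),
                 "amount_escalation", "amount_escalation",
                 "chronic_voucher", "chronic_voucher"),
    target = c(0.35, 0.54,
               0.70, 16.3e6,
               16.9e6, 18.0e6,
               0.88, 25.6e6, 27.2e6,
               0.54, 0.32,
               0.7e6, 0.64,
               3.2e6, 0.50),
    tolerance = c(0.10, 0.10,
                  0.10, 0.10,
                  0.10, 0.20,
                  0.10, 0.10, 0.10,
                  0.10, 0.10,
                  0.10, 0.10,
                  0.10, 0.10))
}

#' Verify a fixture against the published anchors
#'
#' Runs the baseline, amount-escalation and chronic-voucher scenarios and
#' compares each anchor quantity with its published target.
#'
#' @param fixture An `ehcv_fixture` (normally [hk_anchor_fixture()]).
#' @param targets Anchor table as from [hk_anchor_targets()].
#' @return The `targets` data.frame with columns `achieved`, `rel_err` and
#'   `pass` appended.
#' @export
check_hk_fixture <- function(fixture, targets = hk_anchor_targets()) {
  stopifnot(inherits(fixture, "ehcv_fixture"))
  need <- unique(targets$scenario)
  runs <- lapply(stats::setNames(need, need), function(s) {
    run_scenario(simulation_config(fixture, s))$annual
  })
  base <- runs[["baseline"]]
  achieved <- vapply(seq_len(nrow(targets)), function(i) {
    a <- runs[[targets$scenario[i]]]
    nm <- targets$name[i]
    if (startsWith(nm, "d_public_")) {
      yr <- as.integer(sub("^d_public_", "", nm))
      base$visits_public[base$year == yr] -
        a$visits_public[a$year == yr]
    } else {
      extract_anchor(a, nm)
    }
  }, numeric(1))
  targets$achieved <- achieved
  targets$rel_err <- abs(achieved - targets$target) / abs(targets$target)
  targets$pass <- targets$rel_err <= targets$tolerance
  targets
}
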