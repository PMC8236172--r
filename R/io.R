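#' Load a simulation configuration file
#'
#' Reads a YAML or JSON configuration, applies defaults (2009--2032,
#' weekly steps, packaged HK fixture, baseline scenario) and validates it
#' strictly: unknown keys are rejected with a suggestion for the nearest
#' valid key. Recognized keys: `start_year`, `end_year`, `dt_weeks`,
#' `fixture_path`, `scenario_name`, `scenario_path`, `output_path`,
#' `log_level`, `seed`.
#'
#' @param path Path to the configuration file.
#' @return An [simulation_config()] with the extra elements `output_path`,
#'   `log_level` and `seed` attached.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path),
                               call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  known <- c("start_year", "end_year", "dt_weeks", "fixture_path",
             "scenario_name", "scenario_path", "output_path", "log_level",
             "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    hint <- vapply(unknown, function(k) {
      d <- utils::adist(k, known)
      if (min(d) <= 3) sprintf(" (did you mean '%s'?)", known[which.min(d)])
      else ""
    }, character(1))
    stop(sprintf("unknown config key(s): %s",
                 paste0("'", unknown, "'", hint, collapse = ", ")),
         call. = FALSE)
  }
  for (k in c("start_year", "end_year", "dt_weeks", "seed")) {
    if (!is.null(raw[[k]]) && !is.numeric(raw[[k]])) {
      stop(sprintf("config key '%s' must be a number", k), call. = FALSE)
    }
  }
  fixture <- if (is.null(raw$fixture_path)) hk_anchor_fixture() else
    read_fixture_json(raw$fixture_path)
  scenario <- if (!is.null(raw$scenario_path)) {
    read_scenario_file(raw$scenario_path)
  } else if (!is.null(raw$scenario_name)) {
    raw$scenario_name
  } else "baseline"
  config <- simulation_config(
    fixture, scenario,
    start_year = raw$start_year %||% 2009,
    end_year = raw$end_year %||% 2032,
    dt = raw$dt_weeks %||% 1)
  config$output_path <- raw$output_path %||% "results"
  config$log_level <- raw$log_level %||% "INFO"
  config$seed <- as.integer(raw$seed %||% 1L)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a scenario file
#'
#' YAML or JSON with a `name` and an `events` table (`year`, `attribute`,
#' `value`).
#'
#' @param path Scenario file path.
#' @return An [scenario_spec()].
#' @export
read_scenario_file <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  events <- raw$events
  if (!is.null(events) && !is.data.frame(events)) {
    events <- do.call(rbind, lapply(events, as.data.frame))
  }
  scenario_spec(raw$name, events)
}

# serialize-and-md5 of plain R objects; stable across processes for the
# plain lists used here
hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(x, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

#' Export simulation results, comparisons and a run manifest
#'
#' Writes `results.csv` with the fixed column set of the annual output
#' (currency rounded to whole HKD at export; visit counts at full
#' precision so a round-trip read reproduces them exactly), an optional
#' `comparisons.csv`, and `manifest.json` recording the configuration
#' hash, scenario, fixture provenance, package version and timestamp.
#'
#' @param output An `ehcv_output` from [run_scenario()].
#' @param comparisons Optional comparison table from [compare_scenarios()].
#' @param path Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(output, comparisons = NULL, path = "results") {
  stopifnot(inherits(output, "ehcv_output"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  annual <- output$annual
  annual$expenditure_hkd <- round(annual$expenditure_hkd)
  txt <- annual
  for (j in seq_along(txt)) {
    if (is.double(txt[[j]])) txt[[j]] <- sprintf("%.17g", txt[[j]])
  }
  results_path <- file.path(path, "results.csv")
  utils::write.csv(txt, results_path, row.names = FALSE, quote = FALSE)
  files <- c(results = results_path)
  if (!is.null(comparisons) && nrow(comparisons) > 0) {
    cmp_path <- file.path(path, "comparisons.csv")
    utils::write.csv(comparisons, cmp_path, row.names = FALSE, quote = FALSE)
    files <- c(files, comparisons = cmp_path)
  }
  manifest <- list(
    config_hash = hash_object(output$config),
    scenario = output$scenario,
    fixture_provenance = as.list(.last_provenance(output)),
    package_version = as.character(utils::packageVersion("ehcvsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(files))
  manifest_path <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(files, manifest = manifest_path))
}

.last_provenance <- function(output) {
  prov <- output$config$fixture_provenance
  if (is.null(prov)) character() else prov
}

#' Read back an exported results table
#'
#' @param path Path to a `results.csv` written by [write_results()].
#' @return The annual results data.frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path)
}
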