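#' Bundle named scenarios into a suite
#'
#' A `scenario_suite` collects named scenarios — each a schedule config
#' plus an optional list of improvements — under a shared
#' [cascade_config()], with one scenario designated the baseline for
#' excess-treatment comparisons.
#'
#' @param scenarios Named list; each element a list with `schedule` (a
#'   config list for [schedule_from_config()], or a `response_schedule`)
#'   and optionally `improvements` (list of [improvement()] specs or
#'   equivalent config lists).
#' @param baseline Name of the baseline scenario; must be in `scenarios`.
#' @param config Shared [cascade_config()].
#' @return An object of class `scenario_suite`.
#' @export
scenario_suite <- function(scenarios, baseline, config = cascade_config()) {
  if (is.null(names(scenarios)) || any(names(scenarios) == "") ||
      anyDuplicated(names(scenarios))) {
    stop_invalid("scenarios must be uniquely named")
  }
  if (!baseline %in% names(scenarios)) {
    stop_invalid("baseline label '", baseline, "' is not among the scenarios")
  }
  stopifnot(inherits(config, "cascade_config"))
  structure(list(scenarios = scenarios, baseline = baseline, config = config),
            class = "scenario_suite")
}

#' @export
print.scenario_suite <- function(x, ...) {
  cat(sprintf("<scenario_suite: %d scenarios, baseline '%s', cohort %d, coverage %.0f%%>\n",
              length(x$scenarios), x$baseline, x$config$cohort_size,
              100 * x$config$coverage_target))
  invisible(x)
}

improvement_from_config <- function(cfg) {
  if (inherits(cfg, "improvement_spec")) return(cfg)
  improvement(scope = cfg$scope, smd_delta = cfg$smd_delta,
              point_gain = cfg$point_gain, step_index = cfg$step_index,
              replacement_p = cfg$replacement_p)
}

#' Resolve a suite scenario to its effective schedule
#'
#' Builds the scenario's base schedule and applies its improvements in
#' order.
#'
#' @param suite A [scenario_suite()].
#' @param label Scenario name.
#' @return A `response_schedule`.
#' @export
resolve_scenario <- function(suite, label) {
  stopifnot(inherits(suite, "scenario_suite"))
  sc <- suite$scenarios[[label]]
  if (is.null(sc)) stop_invalid("no scenario named '", label, "'")
  sched <- if (inherits(sc$schedule, "response_schedule")) sc$schedule
           else schedule_from_config(sc$schedule)
  for (imp in sc$improvements %||% list()) {
    sched <- apply_improvement(sched, improvement_from_config(imp))
  }
  sched
}

#' Run every scenario in a suite and tabulate the comparison
#'
#' Runs the cascade for each scenario under the suite's shared config and
#' reports, per scenario, the number of steps, total and excess
#' treatments, and the percent reduction in excess treatments versus the
#' baseline scenario (0 for the baseline itself, rounded half up to whole
#' percents; negative if a scenario needs more treatments than the
#' baseline).
#'
#' @param suite A [scenario_suite()].
#' @param strict If `TRUE` (default), a non-converged scenario is an
#'   error; if `FALSE`, its row is flagged (`converged = FALSE`) and its
#'   reduction is `NA`.
#' @return A `data.frame` with one row per scenario, baseline first:
#'   columns `scenario`, `n_steps`, `total_treatments`, `excess_treatments`,
#'   `pct_reduction`, `converged`.
#' @export
#' @examples
#' suite <- read_scenario_suite(
#'   system.file("extdata", "paper.yaml", package = "treatcascade"))
#' run_suite(suite)
run_suite <- function(suite, strict = TRUE) {
  stopifnot(inherits(suite, "scenario_suite"))
  labels <- union(suite$baseline, names(suite$scenarios))
  results <- lapply(labels, function(lab) {
    run_cascade(resolve_scenario(suite, lab), suite$config,
                on_nonconvergence = if (strict) "error" else "flag")
  })
  names(results) <- labels
  base_excess <- results[[suite$baseline]]$excess_treatments
  rows <- lapply(labels, function(lab) {
    r <- results[[lab]]
    data.frame(
      scenario = lab,
      n_steps = r$n_steps,
      total_treatments = r$total_treatments,
      excess_treatments = r$excess_treatments,
      pct_reduction = if (!r$converged) NA_real_ else
        round_half_up(100 * (base_excess - r$excess_treatments) / base_excess),
      converged = r$converged
    )
  })
  tab <- do.call(rbind, rows)
  attr(tab, "results") <- results
  tab
}

#' Read and write scenario suites as YAML or JSON
#'
#' Suites serialise to a plain config document (shared `cohort_size`,
#' `coverage_target`, `rounding`, the `baseline` label, and a named
#' `scenarios` map of schedule/improvement blocks). The format is chosen
#' by file extension: `.yaml`/`.yml` or `.json`. A written suite reads
#' back to an identical suite.
#'
#' @param path File path ending in `.yaml`, `.yml`, or `.json`.
#' @return `read_scenario_suite()`: a [scenario_suite()];
#'   `write_scenario_suite()`: the input, invisibly.
#' @export
read_scenario_suite <- function(path) {
  doc <- switch(tolower(tools::file_ext(path)),
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    stop_invalid("unsupported suite format: ", path)
  )
  cfg <- cascade_config(cohort_size = doc$cohort_size %||% 100,
                        coverage_target = doc$coverage_target %||% 0.99,
                        rounding = doc$rounding %||% "per_step_half_up")
  scenario_suite(doc$scenarios, baseline = doc$baseline, config = cfg)
}

#' @param suite A [scenario_suite()].
#' @rdname read_scenario_suite
#' @export
write_scenario_suite <- function(suite, path) {
  stopifnot(inherits(suite, "scenario_suite"))
  doc <- list(cohort_size = suite$config$cohort_size,
              coverage_target = suite$config$coverage_target,
              rounding = suite$config$rounding,
              baseline = suite$baseline,
              scenarios = suite$scenarios)
  switch(tolower(tools::file_ext(path)),
    yaml = , yml = yaml::write_yaml(doc, path),
    json = jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop_invalid("unsupported suite format: ", path)
  )
  invisible(suite)
}
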