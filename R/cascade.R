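#' Cascade configuration
#'
#' Settings shared by every cascade run: the cohort size, the coverage
#' target (the fraction of the cohort that must have responded before the
#' cascade stops), and the treated-count rounding convention.
#'
#' Two rounding modes are available. Under `per_step_half_up` (the default)
#' the number of patients treated at step \eqn{k} is
#' \eqn{\mathrm{round}(N S_{k-1})} with halves rounded up, where
#' \eqn{S_{k-1}} is the continuous survival (still-unresponsive) fraction —
#' whole patients are treated at each step, but survival itself is always
#' propagated continuously so the ledger never stalls. Under `continuous`
#' the treated counts are the real numbers \eqn{N S_{k-1}} and the total is
#' the partial sum of the survival series.
#'
#' @param cohort_size Number of patients entering the cascade (default 100).
#' @param coverage_target Fraction of the cohort that must respond before
#'   the cascade stops, strictly in (0, 1); default 0.99, i.e. ">99%".
#' @param rounding `"per_step_half_up"` or `"continuous"`.
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(cohort_size = 100, coverage_target = 0.99,
                           rounding = c("per_step_half_up", "continuous")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(cohort_size) || cohort_size < 1 ||
      cohort_size != floor(cohort_size)) {
    stop_invalid("cohort_size must be a positive integer")
  }
  if (!is.numeric(coverage_target) ||
      coverage_target <= 0 || coverage_target >= 1) {
    stop_invalid("coverage_target must lie strictly in (0, 1)")
  }
  structure(list(cohort_size = as.integer(cohort_size),
                 coverage_target = coverage_target, rounding = rounding),
            class = "cascade_config")
}

#' Run the deterministic treatment cascade
#'
#' Pushes a cohort through successive treatment steps. Before step \eqn{k}
#' a fraction \eqn{S_{k-1}} of the cohort is still unresponsive
#' (\eqn{S_0 = 1}); all of them are treated, a fraction \eqn{p_k} responds,
#' and survival updates as \eqn{S_k = S_{k-1}(1 - p_k)}. The cascade stops
#' at the smallest \eqn{K} with \eqn{S_K < 1 - } `coverage_target` — for the
#' default 100-patient cohort and 99% target, "continue while at least one
#' patient in a hundred remains unresponsive".
#'
#' @param schedule A [build_schedule()] response schedule.
#' @param config A [cascade_config()]; defaults to a 100-patient cohort,
#'   >99% coverage, per-step half-up rounding.
#' @param on_nonconvergence What to do if the schedule is exhausted before
#'   the coverage target is reached: `"error"` (default) raises an error
#'   naming the achieved coverage; `"flag"` returns the capped result with
#'   `converged = FALSE` (useful for low-probability sensitivity sweeps).
#' @return An object of class `cascade_result` with elements:
#'   \describe{
#'     \item{steps}{per-step ledger `data.frame`: `step`, `response_prob`,
#'       `survival_before`, `survival_after`, `treated` (integer patients
#'       under `per_step_half_up`, real under `continuous`),
#'       `cumulative_response_pct` (continuous, \eqn{100(1 - S_k)}).}
#'     \item{n_steps}{number of treatment steps delivered.}
#'     \item{total_treatments}{sum of treated counts over all steps.}
#'     \item{excess_treatments}{`total_treatments - cohort_size`: the
#'       treatments beyond the one every patient needs anyway.}
#'     \item{coverage_achieved}{final \eqn{1 - S_K}.}
#'     \item{converged}{whether the coverage target was reached.}
#'   }
#' @export
#' @examples
#' run_cascade(build_schedule("constant", 0.42))              # 237 treatments
#' run_cascade(build_schedule("geometric_decline", 0.5, 0.1)) # 230 treatments
run_cascade <- function(schedule, config = cascade_config(),
                        on_nonconvergence = c("error", "flag")) {
  stopifnot(inherits(schedule, "response_schedule"),
            inherits(config, "cascade_config"))
  on_nonconvergence <- match.arg(on_nonconvergence)
  p <- schedule$probs
  if (length(p) == 0) stop_invalid("schedule is empty")
  n <- config$cohort_size
  thr <- 1 - config$coverage_target

  S_before <- numeric(0); S_after <- numeric(0); treated <- numeric(0)
  S <- 1; k <- 0; converged <- FALSE
  while (k < length(p)) {
    k <- k + 1
    S_before[k] <- S
    treated[k] <- if (config$rounding == "per_step_half_up") {
      round_half_up(n * S)
    } else {
      n * S
    }
    S <- S * (1 - p[k])
    S_after[k] <- S
    if (S < thr) { converged <- TRUE; break }
  }
  if (!converged && on_nonconvergence == "error") {
    stop_invalid(sprintf(
      "schedule exhausted after %d steps with coverage %.4f < target %.4f",
      k, 1 - S, config$coverage_target))
  }

  steps <- data.frame(
    step = seq_len(k),
    response_prob = p[seq_len(k)],
    survival_before = S_before,
    survival_after = S_after,
    treated = treated,
    cumulative_response_pct = 100 * (1 - S_after)
  )
  structure(
    list(steps = steps, n_steps = as.integer(k),
         total_treatments = sum(treated),
         excess_treatments = sum(treated) - n,
         coverage_achieved = 1 - S,
         converged = converged,
         config = config, schedule = schedule),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf(
    "<cascade_result: %d patients, %d steps, %s treatments (%s excess), coverage %.1f%%%s>\n",
    x$config$cohort_size, x$n_steps,
    format(x$total_treatments), format(x$excess_treatments),
    100 * x$coverage_achieved,
    if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}

#' @export
as.data.frame.cascade_result <- function(x, ...) x$steps

#' Expected treatments per patient from the absorbing Markov chain
#'
#' Builds the absorbing Markov chain whose transient states are "awaiting
#' treatment \eqn{k}" (\eqn{k = 1, \dots,} `horizon`), each absorbing into
#' "responded" with probability \eqn{p_k}, and computes the expected number
#' of treatments a patient receives within the horizon as the first-row sum
#' of the fundamental matrix \eqn{N = (I - Q)^{-1}}. Analytically this
#' equals the survival sum \eqn{\sum_{k=0}^{h-1} S_k}; the explicit matrix
#' route exists as an independent cross-check of the cascade ledger.
#'
#' @param schedule A response schedule.
#' @param horizon Number of steps to include; at most `length(schedule)`.
#' @return Expected number of treatments per patient (real).
#' @export
#' @examples
#' markov_expected_treatments(build_schedule("constant", 0.42), 9)
markov_expected_treatments <- function(schedule,
                                       horizon = length(schedule$probs)) {
  stopifnot(inherits(schedule, "response_schedule"))
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 1 ||
      horizon != floor(horizon)) {
    stop_invalid("horizon must be a positive integer")
  }
  if (horizon > length(schedule$probs)) {
    stop_invalid("horizon exceeds schedule length")
  }
  h <- as.integer(horizon)
  p <- schedule$probs[seq_len(h)]
  Q <- matrix(0, h, h)
  if (h > 1) Q[cbind(seq_len(h - 1), seq(2, h))] <- 1 - p[seq_len(h - 1)]
  N <- solve(diag(h) - Q)
  sum(N[1, ])
}

#' Compare two cascade scenarios by excess treatments
#'
#' The benchmark for an innovation's strength: how far it reduces the
#' excess treatments (total minus cohort size) relative to the baseline
#' scenario. The percent reduction is reported as a whole percent, rounded
#' half up.
#'
#' @param baseline,alternative Converged [run_cascade()] results sharing
#'   the same cohort size and coverage target.
#' @return An object of class `scenario_comparison`: `baseline_excess`,
#'   `alternative_excess`, `absolute_reduction`, `pct_reduction`.
#' @export
compare_scenarios <- function(baseline, alternative) {
  stopifnot(inherits(baseline, "cascade_result"),
            inherits(alternative, "cascade_result"))
  if (!baseline$converged || !alternative$converged) {
    stop_invalid("both scenarios must have converged")
  }
  if (baseline$config$cohort_size != alternative$config$cohort_size ||
      baseline$config$coverage_target != alternative$config$coverage_target) {
    stop(errorCondition(
      "scenarios differ in cohort_size or coverage_target and are not comparable",
      class = c("treatcascade_invalid_comparison", "error")))
  }
  ab <- baseline$excess_treatments - alternative$excess_treatments
  structure(
    list(baseline_excess = baseline$excess_treatments,
         alternative_excess = alternative$excess_treatments,
         absolute_reduction = ab,
         pct_reduction = round_half_up(100 * ab / baseline$excess_treatments)),
    class = "scenario_comparison"
  )
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf(
    "<scenario_comparison: excess %s -> %s, reduction %s (%d%%)>\n",
    format(x$baseline_excess), format(x$alternative_excess),
    format(x$absolute_reduction), x$pct_reduction))
  invisible(x)
}

#' Cumulative response curve
#'
#' The fraction of the cohort that has responded by each treatment step,
#' as plotted in the scenario figures: \eqn{100 (1 - S_k)} at step \eqn{k},
#' with a 0% point at step 0. Values are continuous; reports round them
#' half up to whole percents.
#'
#' @param result A [run_cascade()] result.
#' @return A `data.frame` with columns `step` (0..K) and `pct_responded`,
#'   non-decreasing, ending above `100 * coverage_target` for a converged
#'   run.
#' @export
cumulative_response_curve <- function(result) {
  stopifnot(inherits(result, "cascade_result"))
  data.frame(step = c(0L, result$steps$step),
             pct_responded = c(0, result$steps$cumulative_response_pct))
}

#' Export a cascade result
#'
#' `write_cascade_csv()` writes the tidy per-step ledger (columns `step`,
#' `response_prob`, `survival_before`, `treated`,
#' `cumulative_response_pct`); `cascade_summary()` returns the run's totals
#' as a plain list, suitable for JSON export, and `write_cascade_json()`
#' writes it.
#'
#' @param result A [run_cascade()] result.
#' @param path Output file path.
#' @return The input, invisibly (writers); a named list (`cascade_summary`).
#' @export
write_cascade_csv <- function(result, path) {
  stopifnot(inherits(result, "cascade_result"))
  cols <- c("step", "response_prob", "survival_before", "treated",
            "cumulative_response_pct")
  utils::write.csv(result$steps[, cols], path, row.names = FALSE)
  invisible(result)
}

#' @rdname write_cascade_csv
#' @export
cascade_summary <- function(result) {
  stopifnot(inherits(result, "cascade_result"))
  list(n_steps = result$n_steps,
       total_treatments = result$total_treatments,
       excess_treatments = result$excess_treatments,
       mean_treatments_per_patient =
         result$total_treatments / result$config$cohort_size,
       coverage_achieved = result$coverage_achieved,
       converged = result$converged)
}

#' @rdname write_cascade_csv
#' @export
write_cascade_json <- function(result, path) {
  jsonlite::write_json(cascade_summary(result), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(result)
}
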