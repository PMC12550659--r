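#' Per-step response-probability schedules
#'
#' A `response_schedule` holds the ordered probabilities \eqn{p_k} that a
#' patient still unresponsive before step \eqn{k} responds to the treatment
#' offered at that step (step 1 is the first-ever treatment). Schedules come
#' in four kinds:
#'
#' * `constant`: \eqn{p_k = p_1} for all steps — every successive treatment
#'   is as effective as the first.
#' * `geometric_decline`: \eqn{p_k = p_1 (1 - d)^{k-1}} — each new treatment
#'   is a fraction `decline_rate` less effective than the previous one.
#' * `linear_decline`: \eqn{p_k = \max(p_1 - (k-1) d, \mathrm{floor}_p)} —
#'   an absolute per-step drop, floored at `floor_p` to keep probabilities
#'   positive.
#' * `custom`: an arbitrary vector of probabilities supplied via `probs`
#'   (also the kind produced when a single step of a generated schedule is
#'   modified).
#'
#' @param kind One of `"constant"`, `"geometric_decline"`,
#'   `"linear_decline"`, `"custom"`.
#' @param first_response First-step response probability, in (0, 1].
#'   Required for all kinds except `custom`.
#' @param decline_rate Per-step decline: a fraction of the previous step's
#'   rate for `geometric_decline`, an absolute probability decrement for
#'   `linear_decline`. Must satisfy \eqn{0 \le d < 1}. Ignored for
#'   `constant` and `custom`.
#' @param max_steps Number of steps to generate (and a safety cap against
#'   non-terminating cascades). Default 100.
#' @param probs For `kind = "custom"`, the full probability vector.
#' @param floor_p Lower floor for `linear_decline` probabilities
#'   (default 0.01).
#' @return An object of class `response_schedule`: a list with elements
#'   `probs`, `kind`, `first_response`, `decline_rate`, `max_steps`,
#'   `floor_p`.
#' @export
#' @examples
#' build_schedule("constant", 0.42)
#' build_schedule("geometric_decline", 0.50, 0.10)
build_schedule <- function(kind = c("constant", "geometric_decline",
                                    "linear_decline", "custom"),
                           first_response = NULL, decline_rate = 0,
                           max_steps = 100, probs = NULL, floor_p = 0.01) {
  kind <- match.arg(kind)
  if (!is.numeric(max_steps) || length(max_steps) != 1 || max_steps < 1 ||
      max_steps != floor(max_steps)) {
    stop_invalid("max_steps must be a positive integer")
  }
  if (kind != "custom") {
    if (is.null(first_response) || !is.numeric(first_response) ||
        length(first_response) != 1 ||
        first_response <= 0 || first_response > 1) {
      stop_invalid("first_response must be a single probability in (0, 1]")
    }
    if (!is.numeric(decline_rate) || length(decline_rate) != 1 ||
        decline_rate < 0 || decline_rate >= 1) {
      stop_invalid("decline_rate must satisfy 0 <= decline_rate < 1")
    }
  }
  k <- seq_len(max_steps) - 1L
  probs <- switch(kind,
    constant = rep(first_response, max_steps),
    geometric_decline = first_response * (1 - decline_rate)^k,
    linear_decline = pmax(first_response - k * decline_rate, floor_p),
    custom = {
      if (is.null(probs)) stop_invalid("kind = 'custom' requires probs")
      if (length(probs) > max_steps) {
        stop_invalid("custom probs longer than max_steps")
      }
      as.numeric(probs)
    }
  )
  if (any(probs <= 0) || any(probs > 1)) {
    stop_invalid("all step probabilities must lie in (0, 1]")
  }
  if (kind == "custom" && is.null(first_response)) first_response <- probs[1]
  structure(
    list(probs = probs, kind = kind, first_response = first_response,
         decline_rate = decline_rate, max_steps = as.integer(max_steps),
         floor_p = floor_p),
    class = "response_schedule"
  )
}

#' @export
print.response_schedule <- function(x, ...) {
  cat(sprintf("<response_schedule: %s, %d steps>\n", x$kind, length(x$probs)))
  shown <- utils::head(x$probs, 6)
  cat("  p_k:", paste(sprintf("%.4g", shown), collapse = " "),
      if (length(x$probs) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
length.response_schedule <- function(x) length(x$probs)

#' Convert a standardised mean difference gain to a response rate
#'
#' Translates an increment in standardised mean difference (SMD) versus
#' placebo into a new response probability via the Hasselblad–Hedges
#' log-odds transform \eqn{\ln \mathrm{OR} = \mathrm{SMD} \cdot \pi/\sqrt 3}:
#' \deqn{\mathrm{logit}(p_{new}) = \mathrm{logit}(p_{base}) +
#'   \Delta_{SMD} \cdot \pi/\sqrt 3.}
#' A treatment whose SMD exceeds the current treatment's by 0.15 lifts a 50%
#' response rate to 56.8%, i.e. 57% to the nearest percent.
#'
#' @param baseline_response Current response probability, strictly in (0, 1).
#' @param smd_delta Non-negative SMD increment over the current treatment.
#' @return The boosted response probability, in `(baseline_response, 1)` for
#'   `smd_delta > 0`, unrounded.
#' @export
#' @examples
#' smd_to_response(0.50, 0.45 - 0.30)  # 0.5676...
smd_to_response <- function(baseline_response, smd_delta) {
  if (any(!is.finite(baseline_response)) ||
      any(baseline_response <= 0) || any(baseline_response >= 1)) {
    stop_invalid("baseline_response must lie strictly in (0, 1); ",
                 "the logit is undefined at 0 and 1")
  }
  if (any(!is.finite(smd_delta)) || any(smd_delta < 0)) {
    stop_invalid("smd_delta must be non-negative")
  }
  shifted <- stats::plogis(stats::qlogis(baseline_response) +
                             smd_delta * pi / sqrt(3))
  # a zero shift is the exact identity, not a logit round-trip
  ifelse(smd_delta == 0, baseline_response, shifted)
}

#' Specify a treatment innovation
#'
#' An `improvement_spec` describes how an innovation modifies a response
#' schedule: its strength (either an SMD increment, converted with
#' [smd_to_response()] and rounded to the nearest whole percent before use,
#' or a direct percentage-point gain on the first-step rate, or a
#' replacement probability for one step) and its scope:
#'
#' * `first_step_only` — only the first-ever treatment is improved; later
#'   steps keep the original schedule (a better single new treatment).
#' * `all_steps` — every step starts from the boosted first-step rate, with
#'   the original decline re-applied (a system-wide innovation such as
#'   patient–treatment matching or progress feedback).
#' * `single_step` — one chosen step's rate is replaced outright (e.g. a
#'   treatment for treatment-resistant patients that restores the step-3
#'   rate to the first-treatment level).
#'
#' Exactly one of `smd_delta`, `point_gain`, `replacement_p` must be given.
#'
#' @param scope One of `"first_step_only"`, `"all_steps"`, `"single_step"`.
#' @param smd_delta SMD increment over the current first-line treatment.
#' @param point_gain Percentage-point gain on the first-step response rate,
#'   as a fraction (0.07 means +7 points).
#' @param step_index 1-based step to replace; required iff
#'   `scope = "single_step"`.
#' @param replacement_p Replacement probability for `single_step`.
#' @return An object of class `improvement_spec`.
#' @export
#' @examples
#' improvement("first_step_only", smd_delta = 0.15)
#' improvement("all_steps", point_gain = 0.07)
#' improvement("single_step", step_index = 3, replacement_p = 0.50)
improvement <- function(scope = c("first_step_only", "all_steps", "single_step"),
                        smd_delta = NULL, point_gain = NULL,
                        step_index = NULL, replacement_p = NULL) {
  scope <- match.arg(scope)
  drivers <- !vapply(list(smd_delta, point_gain, replacement_p), is.null, TRUE)
  if (sum(drivers) != 1) {
    stop_invalid("exactly one of smd_delta, point_gain, replacement_p ",
                 "must drive the improvement")
  }
  if (scope == "single_step") {
    if (is.null(replacement_p) || is.null(step_index)) {
      stop_invalid("scope = 'single_step' requires step_index and replacement_p")
    }
    if (step_index < 1 || step_index != floor(step_index)) {
      stop_invalid("step_index must be a positive integer")
    }
    if (replacement_p <= 0 || replacement_p > 1) {
      stop_invalid("replacement_p must lie in (0, 1]")
    }
  } else if (!is.null(replacement_p)) {
    stop_invalid("replacement_p is only valid with scope = 'single_step'")
  }
  if (!is.null(smd_delta) && smd_delta < 0) stop_invalid("smd_delta must be >= 0")
  if (!is.null(point_gain) && point_gain < 0) {
    stop_invalid("point_gain must be >= 0")
  }
  structure(
    list(scope = scope, smd_delta = smd_delta, point_gain = point_gain,
         step_index = if (!is.null(step_index)) as.integer(step_index),
         replacement_p = replacement_p),
    class = "improvement_spec"
  )
}

#' Apply an innovation to a response schedule
#'
#' Modifies a schedule according to an [improvement()] spec. SMD-driven
#' gains are first converted with [smd_to_response()] applied to the
#' schedule's first-step rate and rounded to the nearest whole percent
#' (0.5676 becomes 0.57), matching how effect sizes are reported and used
#' in benchmark scenarios; point gains are added to the first-step rate
#' directly. Under `all_steps` the schedule is regenerated from the boosted
#' start with its original kind and decline, so the per-step ratio to the
#' original schedule is constant; under `first_step_only` and `single_step`
#' only the named step changes and the result is a `custom` schedule.
#'
#' @param schedule A [build_schedule()] object.
#' @param spec An [improvement()] object.
#' @return A new `response_schedule`.
#' @export
#' @examples
#' base <- build_schedule("geometric_decline", 0.50, 0.10)
#' apply_improvement(base, improvement("first_step_only", smd_delta = 0.15))
apply_improvement <- function(schedule, spec) {
  stopifnot(inherits(schedule, "response_schedule"),
            inherits(spec, "improvement_spec"))
  if (spec$scope == "single_step") {
    if (spec$step_index > length(schedule$probs)) {
      stop_invalid("step_index exceeds schedule length")
    }
    probs <- schedule$probs
    probs[spec$step_index] <- spec$replacement_p
    return(build_schedule("custom", first_response = probs[1],
                          max_steps = schedule$max_steps, probs = probs,
                          floor_p = schedule$floor_p))
  }
  boosted <- if (!is.null(spec$smd_delta)) {
    round_half_up(smd_to_response(schedule$first_response, spec$smd_delta), 2)
  } else {
    schedule$first_response + spec$point_gain
  }
  if (boosted >= 1) {
    stop_invalid("boosted first-step probability reaches 1; ",
                 "the improvement is too large for this schedule")
  }
  if (spec$scope == "all_steps") {
    build_schedule(schedule$kind, first_response = boosted,
                   decline_rate = schedule$decline_rate,
                   max_steps = schedule$max_steps, floor_p = schedule$floor_p)
  } else {
    probs <- schedule$probs
    probs[1] <- boosted
    build_schedule("custom", first_response = boosted,
                   max_steps = schedule$max_steps, probs = probs,
                   floor_p = schedule$floor_p)
  }
}

#' Serialise a schedule to a plain config list
#'
#' Schedules (and their improvements) travel in scenario files as plain
#' key-value blocks; these helpers convert between the S3 object and that
#' representation. `schedule_from_config()` accepts the list form produced
#' by `schedule_to_config()` or parsed from YAML/JSON.
#'
#' @param schedule A `response_schedule`.
#' @return `schedule_to_config()`: a named list; `schedule_from_config()`:
#'   a `response_schedule`.
#' @export
schedule_to_config <- function(schedule) {
  stopifnot(inherits(schedule, "response_schedule"))
  cfg <- list(kind = schedule$kind,
              first_response = schedule$first_response,
              decline_rate = schedule$decline_rate,
              max_steps = schedule$max_steps,
              floor_p = schedule$floor_p)
  if (schedule$kind == "custom") cfg$probs <- schedule$probs
  cfg
}

#' @param config A named list with at least `kind` and, unless
#'   `kind = "custom"`, `first_response`.
#' @rdname schedule_to_config
#' @export
schedule_from_config <- function(config) {
  build_schedule(kind = config$kind,
                 first_response = config$first_response,
                 decline_rate = config$decline_rate %||% 0,
                 max_steps = config$max_steps %||% 100,
                 probs = config$probs,
                 floor_p = config$floor_p %||% 0.01)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
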