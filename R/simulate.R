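#' Simulate patient-level treatment trajectories
#'
#' Stochastic, patient-level realisation of the cohort cascade: each
#' patient independently undergoes a Bernoulli response trial at step
#' \eqn{k} with probability \eqn{p_k}, moving to the next step on failure,
#' until response or the step cap. The number of treatments a responder
#' receives is the step at which they responded; a censored (never
#' responding) patient receives `cap` treatments.
#'
#' Randomness is drawn as a fixed block of `cap` uniforms per patient, in
#' patient order from a single seeded stream, so patient \eqn{i}'s
#' trajectory is identical whatever `n_patients` is and identical seeds
#' give byte-identical trajectory tables.
#'
#' @param schedule A [build_schedule()] response schedule.
#' @param n_patients Number of patients to simulate.
#' @param cap Maximum number of treatment steps offered; at most
#'   `length(schedule)`. Defaults to the full schedule length.
#' @param seed Integer RNG seed (required, for reproducibility).
#' @return An object of class `trajectory_set`: a list with
#'   `patients` (`data.frame`: `patient_id`, `treatments_received`,
#'   `responded`), `n_patients`, `cap`, `seed`, and `schedule`.
#' @export
#' @examples
#' ts <- simulate_cohort(build_schedule("geometric_decline", 0.5, 0.1),
#'                       n_patients = 1000, cap = 14, seed = 1)
#' mean(ts$patients$treatments_received)
simulate_cohort <- function(schedule, n_patients, cap = length(schedule$probs),
                            seed) {
  stopifnot(inherits(schedule, "response_schedule"))
  if (!is.numeric(n_patients) || n_patients < 1 ||
      n_patients != floor(n_patients)) {
    stop_invalid("n_patients must be a positive integer")
  }
  if (cap < 1 || cap != floor(cap)) stop_invalid("cap must be a positive integer")
  if (cap > length(schedule$probs)) {
    stop_invalid("cap exceeds schedule length")
  }
  if (missing(seed)) stop_invalid("seed is required")
  n <- as.integer(n_patients); cap <- as.integer(cap)
  p <- schedule$probs[seq_len(cap)]

  set.seed(seed)
  # cap draws per patient, patients in columns: patient i always consumes
  # draws (i-1)*cap + 1 .. i*cap, independent of n_patients
  u <- matrix(stats::runif(n * cap), nrow = cap)
  success <- u < p   # recycled down columns: row k compared against p_k

  alive <- rep(TRUE, n)
  treatments <- rep(cap, n)   # censored patients receive all cap treatments
  responded <- rep(FALSE, n)
  for (k in seq_len(cap)) {
    hit <- alive & success[k, ]
    treatments[hit] <- k
    responded[hit] <- TRUE
    alive <- alive & !hit
  }

  structure(
    list(patients = data.frame(patient_id = seq_len(n),
                               treatments_received = treatments,
                               responded = responded),
         n_patients = n, cap = cap, seed = seed, schedule = schedule),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set: %d patients, cap %d, seed %s; %.1f%% responded, mean %.3f treatments>\n",
    x$n_patients, x$cap, format(x$seed),
    100 * mean(x$patients$responded),
    mean(x$patients$treatments_received)))
  invisible(x)
}

#' Recover per-step response rates from simulated trajectories
#'
#' The estimation counterpart of [simulate_cohort()]: at each step the
#' response probability is estimated as (patients responding at that step) /
#' (patients treated at that step), where a patient is treated at step
#' \eqn{k} iff they received at least \eqn{k} treatments. A 95% confidence
#' interval uses the normal approximation, falling back to the exact
#' Clopper–Pearson interval when either the success or failure count is
#' below 5. Steps no patient reached are marked inestimable.
#'
#' @param trajectories A [simulate_cohort()] trajectory set (or one read
#'   back with [read_trajectories()], with the cap attribute intact).
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return A `data.frame` with columns `step`, `n_treated`, `n_responded`,
#'   `estimate`, `ci_lower`, `ci_upper`, `estimable`.
#' @export
estimate_schedule_from_trajectories <- function(trajectories,
                                                conf_level = 0.95) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  d <- trajectories$patients
  if (nrow(d) == 0) stop_invalid("trajectory set is empty")
  cap <- trajectories$cap
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  out <- lapply(seq_len(cap), function(k) {
    n_k <- sum(d$treatments_received >= k)
    x_k <- sum(d$responded & d$treatments_received == k)
    if (n_k == 0) {
      return(data.frame(step = k, n_treated = 0L, n_responded = 0L,
                        estimate = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, estimable = FALSE))
    }
    est <- x_k / n_k
    if (min(x_k, n_k - x_k) < 5) {
      ci <- stats::binom.test(x_k, n_k, conf.level = conf_level)$conf.int
    } else {
      se <- sqrt(est * (1 - est) / n_k)
      ci <- c(max(0, est - z * se), min(1, est + z * se))
    }
    data.frame(step = k, n_treated = n_k, n_responded = x_k,
               estimate = est, ci_lower = ci[1], ci_upper = ci[2],
               estimable = TRUE)
  })
  do.call(rbind, out)
}

#' Export and re-import trajectory tables
#'
#' Trajectories round-trip through plain CSV (columns `patient_id`,
#' `treatments_received`, `responded`) so simulated cohorts can be
#' re-estimated elsewhere. `read_trajectories()` needs the censoring cap
#' that generated the file; the generating schedule is not recoverable from
#' the CSV and is left `NULL`.
#'
#' @param trajectories A `trajectory_set`.
#' @param path CSV file path.
#' @return `write_trajectories()`: the input, invisibly;
#'   `read_trajectories()`: a `trajectory_set` (without a schedule).
#' @export
write_trajectories <- function(trajectories, path) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  utils::write.csv(trajectories$patients, path, row.names = FALSE)
  invisible(trajectories)
}

#' @param cap The step cap used when the trajectories were simulated.
#' @rdname write_trajectories
#' @export
read_trajectories <- function(path, cap) {
  d <- utils::read.csv(path)
  need <- c("patient_id", "treatments_received", "responded")
  if (!all(need %in% names(d))) {
    stop_invalid("trajectory CSV must have columns ",
                 paste(need, collapse = ", "))
  }
  d$responded <- as.logical(d$responded)
  structure(
    list(patients = d[, need], n_patients = nrow(d), cap = as.integer(cap),
         seed = NA_integer_, schedule = NULL),
    class = "trajectory_set"
  )
}
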