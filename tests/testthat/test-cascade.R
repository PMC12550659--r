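# Each benchmark scenario with the step count and treatment totals its
# per-step ledger yields for a 100-patient cohort and a >99% target.
benchmark_cases <- list(
  list(label = "constant 42%", schedule = build_schedule("constant", 0.42),
       n_steps = 9, total = 237),
  list(label = "declining 50%/10%", schedule = paper_baseline(),
       n_steps = 14, total = 230),
  list(label = "first step boosted to 57%",
       schedule = apply_improvement(paper_baseline(),
                                    improvement("first_step_only",
                                                smd_delta = 0.15)),
       n_steps = 13, total = 210),
  list(label = "all steps +7 points",
       schedule = apply_improvement(paper_baseline(),
                                    improvement("all_steps", point_gain = 0.07)),
       n_steps = 10, total = 193),
  list(label = "all steps +14 points",
       schedule = apply_improvement(paper_baseline(),
                                    improvement("all_steps", point_gain = 0.14)),
       n_steps = 7, total = 165),
  list(label = "step 3 restored to 50%",
       schedule = apply_improvement(paper_baseline(),
                                    improvement("single_step", step_index = 3,
                                                replacement_p = 0.50)),
       n_steps = 13, total = 221)
)

test_that("the cascade reproduces every benchmark ledger total", {
  for (case in benchmark_cases) {
    r <- run_cascade(case$schedule)
    expect_equal(r$n_steps, case$n_steps, label = case$label)
    expect_equal(r$total_treatments, case$total, label = case$label)
    expect_equal(r$excess_treatments, case$total - 100, label = case$label)
    expect_true(r$converged)
    expect_gt(r$coverage_achieved, 0.99)
  }
})

test_that("a perfectly effective first treatment ends the cascade at once", {
  r <- run_cascade(build_schedule("custom", probs = 1, max_steps = 1))
  expect_equal(r$n_steps, 1)
  expect_equal(r$total_treatments, 100)
  expect_equal(r$excess_treatments, 0)
})

test_that("continuous rounding matches the geometric-series closed form", {
  r <- run_cascade(build_schedule("constant", 0.42),
                   cascade_config(rounding = "continuous"))
  expect_equal(r$total_treatments, 100 * (1 - 0.58^9) / 0.42,
               tolerance = 1e-10)
  expect_equal(r$total_treatments, 236.3267, tolerance = 1e-4)
})

test_that("the survival ledger conserves the cohort at every step", {
  for (case in benchmark_cases) {
    r <- run_cascade(case$schedule)
    expect_equal(r$steps$cumulative_response_pct / 100 + r$steps$survival_after,
                 rep(1, r$n_steps), tolerance = 1e-15)
    expect_equal(r$steps$survival_before[1], 1)
    expect_equal(r$steps$survival_before[-1],
                 r$steps$survival_after[-r$n_steps])
    expect_true(all(diff(r$steps$survival_after) < 0))
  }
})

test_that("the stopping rule is the smallest K with survival below 1 - coverage", {
  for (case in benchmark_cases) {
    r <- run_cascade(case$schedule)
    thr <- 1 - r$config$coverage_target
    expect_lt(r$steps$survival_after[r$n_steps], thr)
    if (r$n_steps > 1) {
      expect_gte(r$steps$survival_after[r$n_steps - 1], thr)
    }
  }
})

test_that("coverage alternatives shorten the cascade", {
  # relaxing the target to 70% or 80% needs far fewer steps than >99%
  s <- paper_baseline()
  steps <- vapply(c(0.70, 0.80, 0.99), function(cov) {
    run_cascade(s, cascade_config(coverage_target = cov))$n_steps
  }, 1L)
  expect_equal(steps, c(2L, 3L, 14L))
})

test_that("exhausting the schedule errors unless a capped run is requested", {
  short <- build_schedule("constant", 0.3, max_steps = 3)
  expect_error(run_cascade(short), class = "treatcascade_invalid_input")
  r <- run_cascade(short, on_nonconvergence = "flag")
  expect_false(r$converged)
  expect_equal(r$n_steps, 3)
  expect_lt(r$coverage_achieved, 0.99)
})

test_that("fundamental-matrix expectation equals the survival-sum oracle", {
  set.seed(421)
  for (i in 1:25) {
    s <- random_schedule()
    h <- length(s$probs)
    expect_equal(markov_expected_treatments(s, h),
                 survival_sum_oracle(s$probs, h), tolerance = 1e-10)
    # and at a partial horizon
    expect_equal(markov_expected_treatments(s, max(1, h %/% 2)),
                 survival_sum_oracle(s$probs, max(1, h %/% 2)),
                 tolerance = 1e-10)
  }
})

test_that("markov expectation times cohort equals the continuous cascade total", {
  cfg <- cascade_config(rounding = "continuous")
  for (case in benchmark_cases) {
    r <- run_cascade(case$schedule, cfg)
    expect_equal(markov_expected_treatments(case$schedule, r$n_steps) * 100,
                 r$total_treatments, tolerance = 1e-8)
  }
})

test_that("constant-p expectation approaches 1/p at long horizons", {
  for (p in c(0.25, 0.42, 0.5, 0.8)) {
    s <- build_schedule("constant", p, max_steps = 200)
    expect_equal(markov_expected_treatments(s, 200), 1 / p, tolerance = 1e-6)
  }
})

test_that("markov_expected_treatments validates the horizon", {
  s <- paper_baseline()
  expect_error(markov_expected_treatments(s, 0),
               class = "treatcascade_invalid_input")
  expect_error(markov_expected_treatments(s, length(s$probs) + 1),
               class = "treatcascade_invalid_input")
})

test_that("raising any single step probability never increases the continuous total", {
  set.seed(77)
  cfg <- cascade_config(rounding = "continuous")
  for (i in 1:20) {
    s <- random_schedule(len = 40, lo = 0.25, hi = 0.8)
    base_total <- run_cascade(s, cfg)$total_treatments
    k <- sample(1:10, 1)
    probs <- s$probs
    probs[k] <- probs[k] + 0.8 * (1 - probs[k]) * runif(1)
    bumped <- build_schedule("custom", probs = probs, max_steps = 40)
    expect_lte(run_cascade(bumped, cfg)$total_treatments,
               base_total + 1e-9)
  }
})

test_that("per-step rounding and continuous totals differ by at most half a patient per step", {
  for (case in benchmark_cases) {
    hu <- run_cascade(case$schedule)
    co <- run_cascade(case$schedule, cascade_config(rounding = "continuous"))
    expect_lte(abs(hu$total_treatments - co$total_treatments),
               hu$n_steps / 2)
  }
})

test_that("scenario comparisons report the benchmark reductions", {
  base <- run_cascade(paper_baseline())
  first <- run_cascade(benchmark_cases[[3]]$schedule)
  doubled <- run_cascade(benchmark_cases[[5]]$schedule)

  cmp <- compare_scenarios(base, first)
  expect_equal(cmp$baseline_excess, 130)
  expect_equal(cmp$alternative_excess, 110)
  expect_equal(cmp$absolute_reduction, 20)
  expect_equal(cmp$pct_reduction, 15)

  expect_equal(compare_scenarios(base, doubled)$pct_reduction, 50)

  self <- compare_scenarios(base, base)
  expect_equal(self$absolute_reduction, 0)
  expect_equal(self$pct_reduction, 0)
})

test_that("comparisons demand matching configs and converged runs", {
  base <- run_cascade(paper_baseline())
  other <- run_cascade(paper_baseline(), cascade_config(cohort_size = 200))
  expect_error(compare_scenarios(base, other),
               class = "treatcascade_invalid_comparison")
  capped <- run_cascade(build_schedule("constant", 0.3, max_steps = 3),
                        on_nonconvergence = "flag")
  expect_error(compare_scenarios(base, capped),
               class = "treatcascade_invalid_input")
})

test_that("the cumulative response curve starts at zero and climbs past the target", {
  r <- run_cascade(paper_baseline())
  curve <- cumulative_response_curve(r)
  expect_equal(curve$pct_responded[1], 0)
  expect_equal(curve$step[1], 0)
  expect_true(all(diff(curve$pct_responded) >= 0))
  expect_gt(curve$pct_responded[nrow(curve)], 99)
  # after three treatments: 83.64 continuous, 84% to the nearest percent
  expect_equal(curve$pct_responded[curve$step == 3], 83.6375)
  expect_equal(round_half_up(curve$pct_responded[curve$step == 3]), 84)
  # constant scenario: 80.49, reported as 80%
  c42 <- cumulative_response_curve(run_cascade(build_schedule("constant", 0.42)))
  expect_equal(round_half_up(c42$pct_responded[c42$step == 3]), 80)
})

test_that("cascade results export to tidy CSV and a JSON summary", {
  r <- run_cascade(paper_baseline())
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_cascade_csv(r, csv)
  back <- read.csv(csv)
  expect_equal(names(back), c("step", "response_prob", "survival_before",
                              "treated", "cumulative_response_pct"))
  expect_equal(nrow(back), 14)
  expect_equal(sum(back$treated), 230)
  write_cascade_json(r, json)
  summ <- jsonlite::read_json(json)
  expect_equal(summ$total_treatments, 230)
  expect_equal(summ$excess_treatments, 130)
  expect_true(summ$converged)
})
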