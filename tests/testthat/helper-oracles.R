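# Independent oracles, kept deliberately naive so they never share code
# with the implementation they check.

# Expected treatments per patient within a horizon: direct summation of
# the survival products S_0 + S_1 + ... + S_{h-1}.
survival_sum_oracle <- function(probs, horizon) {
  S <- 1
  total <- 0
  for (k in seq_len(horizon)) {
    total <- total + S
    S <- S * (1 - probs[k])
  }
  total
}

# Random converged-by-construction schedules for property tests.
random_schedule <- function(len = sample(5:20, 1), lo = 0.2, hi = 0.9) {
  build_schedule("custom", probs = runif(len, lo, hi), max_steps = len)
}

paper_baseline <- function() build_schedule("geometric_decline", 0.50, 0.10)
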