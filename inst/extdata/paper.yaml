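# Benchmark scenario suite: a 100-patient cohort treated until >99% respond.
# The baseline is the declining-effectiveness scenario (50% first-step
# response, each later treatment 10% less effective than the previous one);
# the other scenarios modify it by one innovation each.
cohort_size: 100
coverage_target: 0.99
rounding: per_step_half_up
baseline: declining_benchmark
scenarios:
  declining_benchmark:
    schedule: {kind: geometric_decline, first_response: 0.50, decline_rate: 0.10, max_steps: 100}
  constant_42:
    # every treatment as effective as the first (42% response throughout)
    schedule: {kind: constant, first_response: 0.42, max_steps: 100}
  first_step_smd045:
    # a new first-line treatment with SMD 0.45 vs placebo, 0.15 above the
    # current 0.30: boosts only the first step (to 57%)
    schedule: {kind: geometric_decline, first_response: 0.50, decline_rate: 0.10, max_steps: 100}
    improvements:
      - {scope: first_step_only, smd_delta: 0.15}
  all_steps_7pt:
    # system-wide innovation: every step 7 points more effective, decline kept
    schedule: {kind: geometric_decline, first_response: 0.50, decline_rate: 0.10, max_steps: 100}
    improvements:
      - {scope: all_steps, point_gain: 0.07}
  all_steps_14pt:
    # the same innovation at doubled strength: +14 points at every step
    schedule: {kind: geometric_decline, first_response: 0.50, decline_rate: 0.10, max_steps: 100}
    improvements:
      - {scope: all_steps, point_gain: 0.14}
  trd_step3_restored:
    # treatment-resistant depression: restore the third step (41% under the
    # baseline decline) to the first-treatment response rate of 50%
    schedule: {kind: geometric_decline, first_response: 0.50, decline_rate: 0.10, max_steps: 100}
    improvements:
      - {scope: single_step, step_index: 3, replacement_p: 0.50}
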