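# Base-case parameters for the psychotropic-deprescribing cost-utility model.
# Arm blocks mirror the published parameter table; the deteriorated-state
# mortality RRs derive from DART-AD cumulative survival (1 + rounded excess
# mortality) and the post-review cost is the mean of the 1- and 6-month
# per-patient drug costs. build_paper_arms() recomputes the same values from
# the raw inputs.
model:
  age_min: 65
  age_max: 90
  horizon_cycles: 1          # 12-month base case, annual cycles
  discount_rate_costs: 0.0
  discount_rate_effects: 0.0
  initial_state_distribution:
    baseline: 0.0
    deteriorated: 1.0        # review targets patients who already have dementia
  sex_mix: 0.75              # 75% women
  population_size: 200
  wtp_threshold: 15000.0
  half_cycle_correction: false
  recurrent_cost_scope: alive
  population_start_age: 87   # cohort mean age 87.09
control:
  incidence: 0.40
  recovery: 0.0
  rr_baseline: 1.0
  rr_deteriorated: 1.51
  cost_baseline: 0.0
  cost_deteriorated: 2265.68
  intervention_recurrent_cost: 0.0
  intervention_oneoff_cost: 0.0
  utility_baseline: 0.70
  utility_deteriorated: 0.27
intervention:
  incidence: 0.40
  recovery: 0.0
  rr_baseline: 1.0
  rr_deteriorated: 1.31
  cost_baseline: 0.0
  cost_deteriorated: 1630.335
  intervention_recurrent_cost: 48.56
  intervention_oneoff_cost: 0.0
  utility_baseline: 0.70
  utility_deteriorated: 0.27
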