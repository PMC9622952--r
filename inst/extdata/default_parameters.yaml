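# Cost-effectiveness model parameters (schema v1)
# Units: costs in 2021 CNY; rates per patient-year; utilities in [0,1];
# discount rate per year; ages and horizons in years.
config_version: 1
arms:
  edaravone:
    name: edaravone
    day90:
      mrs01: 0.59
      mrs23: 0.281
      mrs45: 0.112
      dead: 0.017
    arm_size: 600.0
    drug_course_cost: 1103.480000000000018
  edaravone_dexborneol:
    name: edaravone_dexborneol
    day90:
      mrs01: 0.672
      mrs23: 0.237
      mrs45: 0.078
      dead: 0.014
    arm_size: 600.0
    drug_course_cost: 4099.199999999999818
control: edaravone
intervention: edaravone_dexborneol
efficacy_or:
  odds_ratio: 1.42
  ci_low: 1.12
  ci_high: 1.81
transitions:
  annual_recurrence_rate: 0.12
  recurrence_growth_rr: 1.019
  recurrent_death_prob: 0.21
  nonstroke_death_hr:
    mrs01: 1.0
    mrs23: 1.19
    mrs45: 2.04
costs:
  injection_cost: 7.25
  n_administrations: 28.0
  hosp_onetime:
    mrs01: 12593.510000000000218
    mrs25: 16650.770000000000437
    dead: 14269.819999999999709
  posthosp_annual:
    mrs01: 8954.0
    mrs25: 13623.399999999999636
  recurrence_cost: 28987.049999999999272
utilities:
  preset: table1
  state_utility:
    mrs01: 0.8
    mrs23: 0.58
    mrs45: 0.28
    dead: 0.0
  recurrence_utility: 0.34
econ:
  discount_rate: 0.05
  wtp_per_qaly: 121464.0
  horizon_years: 30
  cycle_length_years: 1.0
  entry_age: 63
  half_cycle_correction: yes
life_table:
  a: 2.0e-05
  b: 0.085
  age_min: 63
  age_max: 93
switches:
  mortality_hr_mode: hazard_power
  rate_to_prob: exponential
  first_cycle_mode: fractional_075
  discount_timing: end_of_cycle
  psa_efficacy_mode: dirichlet
recurrence_destination:
- mrs01: 1.0
  mrs23: 0.0
  mrs45: 0.0
- mrs01: 0.0
  mrs23: 1.0
  mrs45: 0.0
- mrs01: 0.0
  mrs23: 0.0
  mrs45: 1.0
ranges:
- parameter_id: or_mrs01
  base: 1.42
  low: 1.12
  high: 1.81
  family: lognormal
- parameter_id: recurrence_rate
  base: 0.12
  low: 0.1123
  high: 0.1241
  family: beta
- parameter_id: recurrence_growth
  base: 1.019
  low: 1.014
  high: 1.024
  family: lognormal
- parameter_id: recurrent_death
  base: 0.21
  low: 0.1887
  high: 0.2316
  family: beta
- parameter_id: hr_mrs01
  base: 1.0
  low: 1.0
  high: 1.2
  family: lognormal
- parameter_id: hr_mrs23
  base: 1.19
  low: 1.1
  high: 1.3
  family: lognormal
- parameter_id: hr_mrs45
  base: 2.04
  low: 1.4
  high: 3.0
  family: lognormal
- parameter_id: cost_drug_dexborneol
  base: 4099.199999999999818
  low: 3279.360000000000127
  high: 4099.199999999999818
  family: gamma
- parameter_id: cost_drug_edaravone
  base: 1103.480000000000018
  low: 546.0
  high: 5420.800000000000182
  family: gamma
- parameter_id: cost_injection
  base: 7.25
  low: 5.0
  high: 12.0
  family: gamma
- parameter_id: cost_hosp_mrs01
  base: 12593.510000000000218
  low: 7273.720000000000255
  high: 15856.239999999999782
  family: gamma
- parameter_id: cost_hosp_mrs25
  base: 16650.770000000000437
  low: 9150.979999999999563
  high: 21834.389999999999418
  family: gamma
- parameter_id: cost_hosp_dead
  base: 14269.819999999999709
  low: 6705.260000000000218
  high: 18861.180000000000291
  family: gamma
- parameter_id: cost_posthosp_mrs01
  base: 8954.0
  low: 2681.050000000000182
  high: 11420.8799999999992
  family: gamma
- parameter_id: cost_posthosp_mrs25
  base: 13623.399999999999636
  low: 3426.659999999999854
  high: 17131.990000000001601
  family: gamma
- parameter_id: cost_recurrence
  base: 28987.049999999999272
  low: 26088.349999999998545
  high: 31885.759999999998399
  family: gamma
- parameter_id: utility_mrs01
  base: 0.8
  low: 0.8
  high: 0.95
  family: beta
- parameter_id: utility_mrs23
  base: 0.58
  low: 0.56
  high: 0.78
  family: beta
- parameter_id: utility_mrs45
  base: 0.28
  low: 0.05
  high: 0.36
  family: beta
- parameter_id: utility_recurrence
  base: 0.34
  low: 0.27
  high: 0.42
  family: beta
- parameter_id: discount_rate
  base: 0.05
  low: 0.0
  high: 0.08
  family: fixed

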