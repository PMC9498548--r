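parameters:
  population_init: 6910840.0
  diabetes_rate: 0.8
  hypertension_rate: 0.8
  diet_rate: 0.8
  lifestyle_rate: 0.8
  base_progression_rate_stage1: 8.0
  base_progression_rate_stage2: 6.0
  base_progression_rate_stage3: 4.0
  base_progression_rate_stage4: 3.0
  base_progression_rate_stage5: 2.0
  dialysis_rate: 40.0
  transplant_rate: 15.0
  esrd_death_rate: 10.0
  patient_bias_stage1: 0.1
  provider_bias_stage1: 0.8
  nephrologist_bias_stage1: 0.05
  system_bias_stage1: 0.1
  patient_bias_stage2: 0.1
  provider_bias_stage2: 0.08
  nephrologist_bias_stage2: 0.05
  system_bias_stage2: 0.1
  patient_bias_stage3: 0.1
  provider_bias_stage3: 0.16
  nephrologist_bias_stage3: 0.05
  system_bias_stage3: 0.1
  patient_bias_stage4: 0.1
  provider_bias_stage4: 0.073
  nephrologist_bias_stage4: 0.05
  system_bias_stage4: 0.1
  patient_bias_stage5: 0.1
  provider_bias_stage5: 0.152
  nephrologist_bias_stage5: 0.05
  system_bias_stage5: 0.1
  patient_bias_esrd: 0.1
  provider_bias_esrd: 0.33
  nephrologist_bias_esrd: 0.05
  system_bias_esrd: 0.1
  monitored_slowdown: 0.25
  screening_coverage: 0.3
  bias_gain: 0.5
simulation:
  t_start: 2010.0
  t_end: 2022.0
  dt: 0.0625
scenarios:
- name: current
  overrides:
    diabetes_rate: 1.15
    hypertension_rate: 1.25
- name: stage1-bias
  overrides:
    provider_bias_stage1: 1.3
- name: stage2-bias
  overrides:
    provider_bias_stage2: 1.55
- name: stage3-bias
  overrides:
    provider_bias_stage3: 1.32
- name: stage4-bias
  overrides:
    provider_bias_stage4: 1.151
- name: stage5-bias
  overrides:
    provider_bias_stage5: 0.275
- name: esrd-bias
  overrides:
    provider_bias_esrd: 0.72
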