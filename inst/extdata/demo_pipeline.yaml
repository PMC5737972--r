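# Demo pipeline configuration: a small synthetic registry run end to end.
# Any sim_config() argument expressible as YAML may appear under 'sim';
# function-valued arguments (e.g. baseline_hazard) keep their defaults.
seed: 1
cutoff: 64
participation: 0.70
basis: quadratic
sim:
  cohort_size: 1000
  participation: 0.70
  lead_mean: 2
  stage_shift: 0.5
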