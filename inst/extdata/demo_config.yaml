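# Demo run configuration: small cohort with an implanted interaction at
# node 4. Keys mirror default_run_config().
seed: 7
n_subjects: 48
n_regions: 10
n_timepoints: 200
beta: 6.0
alpha: 0.05
ss_type: 3.0
criteria:
  - total
base_correlation: 0.2
background_correlation: 0.1
effect_node: 4
n_effect_neighbors: 3
obesity_main_delta: 0.0
interaction_delta: 0.4
confound_age_slope: 0.0
confound_sex_delta: 0.0
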