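# Toy configuration for fast tests and cross-checks: a 40-adult population
# with 4 CI classes and 2 immature stages.  Not a biological scenario.
strains:
  wAlbAB:
    wild_type: true
  ARwP:
    wild_type: false
ci:
  K: 4
  decay_enabled: true
  decay_breaks: [2, 3]
  decay_levels: [1.0, 0.67, 0.0]
fitness:
  expected:
    lambda_birth: 0.24
    mu_M: 0.125
    mating_rate: 0.7
    immature_mean_duration: 6.0
    immature_shape: 2
    ci_aging_rate: 1.0
    feasibility_ratio: 0.999
population:
  N0: 40
migration:
  migration_total: 0
policy:
  policy: maintain
  contamination_rate: 0.01
  overflooding_ratio: 5
  release_interval: 7
  omega_star: 0.4
  resume_factor: 0.8
  suppression_fraction: 0.10
  horizon_days: 120
  max_release_days: 90
  min_release_days: 14
cage:
  max_days: 100
  runout_days: 30
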