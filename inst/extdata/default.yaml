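# Default model configuration.
#
# The wild Aedes albopictus population carries the natural wAlbA/wAlbB double
# infection (wAlbAB); ARwP is the artificial wPip infection used for
# releases.  Fitness values are point choices for an urban-block population:
# the female death rate is derived from the feasibility constraint at ratio
# 0.999 and is NOT set here (the expected set yields a 9.6-day female
# lifespan).  Rates are per day.
strains:
  wAlbAB:
    wild_type: true
  ARwP:
    wild_type: false
ci:
  K: 20
  decay_enabled: true
  decay_breaks: [14, 19]     # full CI through class 14, partial to 19, none at 20
  decay_levels: [1.0, 0.67, 0.0]
fitness:
  expected:
    lambda_birth: 0.24       # future adults per mated female per day
    mu_M: 0.125              # male death rate (8-day mean lifespan)
    mating_rate: 0.7         # per unmated female per day
    immature_mean_duration: 17.5
    immature_shape: 5
    ci_aging_rate: 1.0       # CI class progression, classes track days
    feasibility_ratio: 0.999
  low:                       # faster turnover, shorter lifespans
    lambda_birth: 0.30
    mu_M: 0.15
    mating_rate: 0.7
    immature_mean_duration: 15.0
    immature_shape: 5
    ci_aging_rate: 1.0
    feasibility_ratio: 0.999
  high:                      # slower turnover, longer lifespans
    lambda_birth: 0.19
    mu_M: 0.105
    mating_rate: 0.7
    immature_mean_duration: 20.0
    immature_shape: 5
    ci_aging_rate: 1.0
    feasibility_ratio: 0.999
population:
  N0: 420
migration:
  migration_total: 0         # adults per week; study values 0 / 2 / 10
policy:
  policy: maintain
  contamination_rate: 0.01
  overflooding_ratio: 5
  release_interval: 7
  omega_star: 0.4
  resume_factor: 0.8
  suppression_fraction: 0.10
  horizon_days: 920
  max_release_days: 730
  min_release_days: 100
cage:
  max_days: 500
  runout_days: 180
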