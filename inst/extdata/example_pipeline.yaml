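# Annotated pipeline configuration.  Every key is optional; unknown keys
# are rejected.  Run with:
#   vitalink run --config example_pipeline.yaml --seed 1 --out runs/demo
scale: 0.1          # cohort size multiplier (1 = full ~421k-birth cohort)
seed: 1             # master seed; each stage derives a named substream
# cohort_file: my_cohort.yaml     # alternative cohort calibration
# ice_file: my_ice_groups.yaml    # alternative cause grouping
alpha: 0.05         # CI non-coverage (0.05 = 95% intervals)
suppress_at: 5      # suppress rates with numerator <= 5
corruption:         # overrides of corruption_config() defaults
  p_identifier_missing: 0.15
  p_postal_typo: 0.03
  p_dob_shift: 0.05
linkage:            # overrides of linkage_config() defaults
  blocking: dob_pm1
  upper_posterior: 0.9
  lower_posterior: 0.1
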