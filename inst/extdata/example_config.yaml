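# Example run configuration.
# Instrument/method metadata below is echoed into reports for provenance
# only; nothing is computed from it.
seed: 1
injection_volume_ml: 0.010
dilution_factor: 1
rt_tolerance_min: 0.3
mass_tolerance_da: 5
process_threshold_intermediate: 0.04
process_threshold_drug_substance: 0.01
vp_ref_rt:
  VP4: 4.335
  VP1: 5.669
  VP2: 7.079
  VP0: 7.527
  VP3: 8.775
# slope matches the synthetic generator's closed form:
# responsePerTrp (1e-6) x 60 copies x 27 tryptophan-equivalents per capsid
standard_curve:
  slope: 1.62e-3
  intercept: 0.0
  range: [2.78e9, 1.04e11]
method_metadata:
  flow_rate_ml_min: 0.4
  column_temp_c: 80
  gradient:  # time_min, pct_b
    - [0.0, 25]
    - [0.5, 25]
    - [4.5, 42]
    - [10.5, 48]
    - [11.5, 80]
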