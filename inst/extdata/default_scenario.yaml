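# Default synthetic competence-induction scenario: three timepoints, one
# reporter strain whose induced fraction grows from 0 to 0.05, and two
# control strains that stay at 0. Values omitted here fall back to the
# package defaults (see default_config()).
scenario:
  seed: 1
  timepoints_h: [2, 7, 20]
  strains:
    - name: comEAEC_reporter
      induced_fraction: [0.0, 0.02, 0.05]
    - name: constitutive_control
      induced_fraction: [0.0, 0.0, 0.0]
    - name: wildtype
      induced_fraction: [0.0, 0.0, 0.0]
fc:
  n_events: 100000
  channel: PE-A
microscopy:
  n_fields: 2
stats:
  levels_fc: [75, 99]
  levels_microscopy: [95, 99]
  subsample_fc: 250
  subsample_microscopy: 150
  reference_timepoint: 2
  late_timepoint: 20
kinetics:
  window_size: 3
  detection_limit: 1.0e-9
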