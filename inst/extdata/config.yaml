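epoch_short_s: 1.0
epoch_long_s: 15.0
bout_max_rest_s: 5.0
long_walk_min_s: 60.0
long_walk_min_cadence_spm: 80.0
all_walk_min_steps: 5.0
valid_day_min_wear_h: 10.0
clinical_threshold_min: 20.0
cut_points:
  # PLACEHOLDER values calibrated to the package's synthetic generator.
  # For real-data analyses, transcribe the published older-adult wrist AVM
  # cut points from their source and update the provenance note; the
  # pipeline never silently hard-codes intensity thresholds.
  light_mg: 30.0
  moderate_mg: 100.0
  provenance: "walkanchor synthetic defaults; replace with published older-adult wrist AVM cut points for real-data analyses"
seed: 1
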