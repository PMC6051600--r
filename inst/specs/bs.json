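{
  "model_id": "BS",
  "label": "Biologic Syndrome",
  "domains": ["weight_loss_domain", "bs_exhaustion", "bs_low_energy", "bs_slowness", "bs_weakness"],
  "items": null,
  "divisor": 0,
  "index_range": [0, 5],
  "cutoff": 3,
  "age_eligibility": 65,
  "input_columns": ["weight_loss", "underweight", "scaled_everything_effort", "cannot_get_going", "activity_score", "walk_time_8ft", "grip_strength", "height", "weight_kg", "sex_male"]
}
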