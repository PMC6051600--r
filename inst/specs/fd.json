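{
  "model_id": "FD",
  "label": "Functional Domains",
  "domains": ["fd_physical", "weight_loss_domain", "fd_cognitive", "sensory"],
  "items": null,
  "divisor": 0,
  "index_range": [0, 4],
  "cutoff": 2,
  "age_eligibility": 65,
  "input_columns": ["dizziness", "lift_difficulty", "climb_difficulty", "weight_loss", "underweight", "cognitive_impairment", "memory_problem", "poor_hearing", "poor_eyesight"]
}
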