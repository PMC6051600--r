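{
  "model_id": "burden",
  "label": "Burden (deficit accumulation)",
  "items": ["hypertension", "diabetes", "heart_disease", "stroke_history", "lung_disease", "cancer_history", "arthritis", "incontinence", "fall_history", "adl_bathing", "adl_dressing", "adl_eating", "iadl_meals", "iadl_shopping", "iadl_medications", "scaled_self_rated_health", "scaled_mobility_difficulty", "scaled_adl_difficulty", "scaled_iadl_difficulty", "scaled_depressive_symptoms", "scaled_pain_level", "scaled_fatigue_scale", "scaled_social_activity", "burden_cognition"],
  "divisor": 24,
  "index_range": [0, 1],
  "cutoff": 0.2,
  "age_eligibility": 70,
  "input_columns": ["hypertension", "diabetes", "heart_disease", "stroke_history", "lung_disease", "cancer_history", "arthritis", "incontinence", "fall_history", "adl_bathing", "adl_dressing", "adl_eating", "iadl_meals", "iadl_shopping", "iadl_medications", "scaled_self_rated_health", "scaled_mobility_difficulty", "scaled_adl_difficulty", "scaled_iadl_difficulty", "scaled_depressive_symptoms", "scaled_pain_level", "scaled_fatigue_scale", "scaled_social_activity", "scaled_cognition_performance", "scaled_cognition_proxy"]
}
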