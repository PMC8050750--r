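{
  "base": {
    "resource_type": "Observation",
    "code_selector": {
      "codes": [
        "2823-3"
      ],
      "match": "exact",
      "system": "http://loinc.org"
    }
  },
  "criteria": [
    {
      "polarity": "include",
      "resource_type": "Procedure",
      "code_selector": {
        "codes": [
          "6-002.q"
        ],
        "match": "prefix"
      },
      "mode": "window",
      "window_before_days": 7,
      "window_after_days": 7,
      "use_encounter_period": true
    }
  ],
  "feature_set": {
    "aggregation": "none",
    "columns": [
      "patient_id",
      "gender",
      "age",
      "value",
      "unit",
      "code",
      "time"
    ]
  }
}
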