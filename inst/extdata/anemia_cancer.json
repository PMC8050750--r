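{
  "base": {
    "resource_type": "Observation",
    "code_selector": {
      "codes": [
        "718-7"
      ],
      "match": "exact",
      "system": "http://loinc.org"
    }
  },
  "criteria": [
    {
      "polarity": "exclude",
      "resource_type": "Condition",
      "code_selector": {
        "codes": [
          "C"
        ],
        "match": "prefix"
      },
      "mode": "ever",
      "use_encounter_period": true
    }
  ],
  "feature_set": {
    "aggregation": "min_per_patient",
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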