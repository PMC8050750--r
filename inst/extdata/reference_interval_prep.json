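{
  "base": {
    "resource_type": "Observation",
    "code_selector": {
      "codes": [
        "718-7"
      ],
      "match": "exact",
      "system": "http://loinc.org"
    },
    "patient_filter": {
      "genders": [
        "male"
      ],
      "age_min": 18,
      "age_max": 65
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
    },
    {
      "polarity": "exclude",
      "resource_type": "Procedure",
      "code_selector": {
        "codes": [
          "8-80"
        ],
        "match": "prefix"
      },
      "mode": "ever",
      "use_encounter_period": true
    },
    {
      "polarity": "exclude",
      "resource_type": "Observation",
      "code_selector": {
        "codes": [
          "718-7"
        ],
        "match": "exact",
        "system": "http://loinc.org"
      },
      "value_filter": {
        "comparator": "lt",
        "threshold": 8,
        "unit": "g/dL"
      },
      "mode": "ever",
      "use_encounter_period": true
    },
    {
      "polarity": "exclude",
      "resource_type": "Procedure",
      "code_selector": {
        "codes": [
          "5-"
        ],
        "match": "prefix"
      },
      "mode": "window",
      "window_before_days": 90,
      "window_after_days": 90,
      "use_encounter_period": true
    }
  ],
  "feature_set": {
    "aggregation": "random_one_per_patient",
    "columns": [
      "patient_id",
      "gender",
      "age",
      "value",
      "unit",
      "code",
      "time"
    ],
    "random_seed": 1
  }
}
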