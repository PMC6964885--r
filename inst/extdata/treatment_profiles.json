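[
  {
    "name": "infliximab",
    "remission_median": 0.48,
    "remission_lo": 0.33,
    "remission_hi": 0.64,
    "wdae_median": 0.12,
    "wdae_lo": 0.063,
    "wdae_hi": 0.25,
    "dosing": "IV infusion every 8 weeks",
    "prednisone": "Yes",
    "blood_liver": "No",
    "infection_cancer": "Yes"
  },
  {
    "name": "infliximab_azathioprine",
    "remission_median": 0.63,
    "remission_lo": 0.44,
    "remission_hi": 0.8,
    "wdae_median": 0.12,
    "wdae_lo": 0.045,
    "wdae_hi": 0.27,
    "dosing": "daily tablets + IV infusion every 8 weeks",
    "prednisone": "Yes",
    "blood_liver": "Yes",
    "infection_cancer": "Yes"
  },
  {
    "name": "adalimumab",
    "remission_median": 0.61,
    "remission_lo": 0.46,
    "remission_hi": 0.75,
    "wdae_median": 0.023,
    "wdae_lo": 0.012,
    "wdae_hi": 0.042,
    "dosing": "injection every 2 weeks",
    "prednisone": "Yes",
    "blood_liver": "No",
    "infection_cancer": "Yes"
  },
  {
    "name": "vedolizumab",
    "remission_median": 0.41,
    "remission_lo": 0.27,
    "remission_hi": 0.57,
    "wdae_median": 0.03,
    "wdae_lo": 0.014,
    "wdae_hi": 0.061,
    "dosing": "IV infusion every 8 weeks",
    "prednisone": "Yes",
    "blood_liver": "No",
    "infection_cancer": "No"
  },
  {
    "name": "azathioprine",
    "remission_median": 0.36,
    "remission_lo": 0.24,
    "remission_hi": 0.49,
    "wdae_median": 0.15,
    "wdae_lo": 0.079,
    "wdae_hi": 0.26,
    "dosing": "daily tablets",
    "prednisone": "Yes",
    "blood_liver": "Yes",
    "infection_cancer": "Yes"
  },
  {
    "name": "methotrexate",
    "remission_median": 0.42,
    "remission_lo": 0.25,
    "remission_hi": 0.61,
    "wdae_median": 0.38,
    "wdae_lo": 0.12,
    "wdae_hi": 0.83,
    "dosing": "weekly injection",
    "prednisone": "Yes",
    "blood_liver": "Yes",
    "infection_cancer": "Yes"
  }
]
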