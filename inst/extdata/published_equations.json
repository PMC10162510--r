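{
  "version": "1.0",
  "notes": "Previously published multiple linear regression equations predicting Wingate peak power (PP) and mean power (MP), watts, from standardised graded-exercise-test features at 85/90/100% of age-predicted HRmax. Coefficients apply to z-scored features; intercepts are watts at the standardised origin.",
  "equations": [
    {
      "outcome": "pp", "level": 0.85, "intercept": 644,
      "terms": [
        {"feature": "vo2_abs", "coefficient": 225},
        {"feature": "vo2_rel", "coefficient": -87},
        {"feature": "slope_speed_time", "coefficient": -26}
      ],
      "provenance": "published peak-power regression, 85% of age-predicted HRmax"
    },
    {
      "outcome": "pp", "level": 0.90, "intercept": 642,
      "terms": [
        {"feature": "vo2_abs", "coefficient": 193},
        {"feature": "vo2_at_rel", "coefficient": -99},
        {"feature": "slope_speed_time", "coefficient": -25},
        {"feature": "vo2_at_abs", "coefficient": 34}
      ],
      "provenance": "published peak-power regression, 90% of age-predicted HRmax"
    },
    {
      "outcome": "pp", "level": 1.00, "intercept": 645,
      "terms": [
        {"feature": "vo2_abs", "coefficient": 225},
        {"feature": "vo2_rel", "coefficient": -100},
        {"feature": "slope_speed", "coefficient": 67},
        {"feature": "slope_speed_time", "coefficient": -32}
      ],
      "provenance": "published peak-power regression, 100% of age-predicted HRmax"
    },
    {
      "outcome": "mp", "level": 0.85, "intercept": 475,
      "terms": [
        {"feature": "vo2_abs", "coefficient": 154},
        {"feature": "vo2_at_rel", "coefficient": -93},
        {"feature": "time", "coefficient": 27},
        {"feature": "vo2_at_abs", "coefficient": 6}
      ],
      "provenance": "published mean-power regression, 85% of age-predicted HRmax"
    },
    {
      "outcome": "mp", "level": 0.90, "intercept": 478,
      "terms": [
        {"feature": "vo2_abs", "coefficient": 167},
        {"feature": "vo2_at_rel", "coefficient": -101},
        {"feature": "time", "coefficient": 33}
      ],
      "provenance": "published mean-power regression, 90% of age-predicted HRmax"
    },
    {
      "outcome": "mp", "level": 1.00, "intercept": 478,
      "terms": [
        {"feature": "vo2_abs", "coefficient": 156},
        {"feature": "vo2_rel", "coefficient": -39}
      ],
      "provenance": "published mean-power regression, 100% of age-predicted HRmax"
    }
  ]
}
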