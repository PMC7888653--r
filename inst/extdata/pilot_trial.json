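{
  "records": [
    {
      "dog": "Florin",
      "sets": [
        {"target_position": 2, "reward_scheme": "positive_bias", "runs": ["-", "X", "T"]},
        {"target_position": 1, "reward_scheme": "positive_bias", "runs": ["X", "X"]},
        {"target_position": 3, "reward_scheme": "positive_bias", "runs": ["-", "T"]},
        {"target_position": 2, "reward_scheme": "positive_bias", "runs": ["X", "-", "-", "X"]},
        {"target_position": 3, "reward_scheme": "balanced", "runs": ["T"]},
        {"target_position": 2, "reward_scheme": "balanced", "runs": ["-", "T"]},
        {"target_position": 3, "reward_scheme": "balanced", "runs": ["-", "T"]}
      ]
    },
    {
      "dog": "Midas",
      "sets": [
        {"target_position": 3, "reward_scheme": "positive_bias", "runs": ["T"]},
        {"target_position": 1, "reward_scheme": "positive_bias", "runs": ["X", "X"]},
        {"target_position": 2, "reward_scheme": "balanced", "runs": ["X", "T"]},
        {"target_position": 1, "reward_scheme": "balanced", "runs": ["-", "X", "X"]},
        {"target_position": 2, "reward_scheme": "balanced", "runs": ["X", "-", "-", "T"]},
        {"target_position": 1, "reward_scheme": "balanced", "runs": ["X", "T"]},
        {"target_position": 3, "reward_scheme": "balanced", "runs": ["T"]}
      ],
      "overrides": {"false_positives": 6, "controls_presented": 20}
    }
  ]
}
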