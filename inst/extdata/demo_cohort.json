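{
  "week_start": "2015-06-01",
  "dose_mode": "personal",
  "participants": [
    {
      "participant_id": "P01",
      "heat_coefficient": 0.0068,
      "dose_days": [1, 3, 4, 5, 7]
    },
    {
      "participant_id": "P02",
      "heat_coefficient": 0.005,
      "hr_rest": 62,
      "dose_days": [2, 3, 4, 6, 7],
      "truncated_days": [1]
    },
    {
      "participant_id": "P03",
      "heat_coefficient": 0.0042,
      "hr_gain": 0.38,
      "dose_days": [1, 2, 3, 5, 6, 7]
    }
  ]
}
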