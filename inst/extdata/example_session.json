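{
  "event_profile": {
    "user_id": "example01",
    "qualities": ["heavy", "tight"],
    "locations": ["chest_center"],
    "radiation": ["jaw_left"],
    "associated": ["shortness_of_breath"],
    "recorded_at": "2020-03-31T10:00:00Z"
  },
  "heart_checks": [
    {
      "user_id": "example01",
      "episodes": [
        {
          "qualities": ["heavy"],
          "locations": ["chest_center"],
          "radiation": [],
          "associated": [],
          "onset_at": "2020-04-02T22:00:00Z"
        }
      ],
      "asked_at": "2020-04-03T10:00:00Z"
    }
  ],
  "wellness_checks": [
    {
      "user_id": "example01",
      "scores": {
        "general_activities": 7,
        "work": 6,
        "walking": 8,
        "mood": 3,
        "relations": 7,
        "sleep": 4,
        "enjoyment": 6
      },
      "asked_at": "2020-04-07T10:00:00Z"
    }
  ]
}
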