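{
  "comment": "Canonical wheelvault experiment configuration. Mirrors the defaults of pipeline_config(); every key is optional.",
  "synth": {
    "seed": 42,
    "n_days": 8,
    "performances_per_day": 13,
    "ride_time_range": [3, 7],
    "knee_angle_range": [145, 180],
    "knee_penalty_rate": 0.015,
    "straight_leg_threshold": 162.5,
    "judge_noise_sd": 0.05,
    "flow_noise_sd": 0.3,
    "pose_jitter_sd": 3,
    "meta": { "fps": 60, "width": 160, "height": 120, "motion_direction": "leftward" }
  },
  "detector": {
    "eps": 1.0,
    "window": 30,
    "min_contact_s": 0.5,
    "lookback": 10,
    "mag_lo": 5.5,
    "mag_hi": 15
  },
  "model": { "n_trees": 100, "threshold": 0.1, "n_test_days": 2, "seed": 0 },
  "stats": {
    "cond_a": "time_on_wheel<=4.935",
    "cond_b": "knee_pikemount>162.5",
    "control": "I",
    "alpha": 0.05
  }
}
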