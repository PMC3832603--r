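{
  "channel": "blue",
  "camera": "Canon 40D",
  "bit_depth": 8,
  "g_max": 250,
  "p_min": 31,
  "e_max_umol": 0.0124,
  "biexp": {
    "b": 75.8, "c": 5240, "d": 179, "g": 1065,
    "ci_halfwidths": {"b": 19, "c": 1460, "d": 20, "g": 110},
    "scale": "original"
  },
  "bezier": {
    "control_points": [
      {"x": 1.25e-2, "y": 2.18e-1, "ci_x": 2.49e-4, "ci_y": 3.65e-3},
      {"x": 1.45e-2, "y": 3.11e-1, "ci_x": 8.46e-4, "ci_y": 5.61e-3},
      {"x": 5.40e-2, "y": 8.28e-1, "ci_x": 1.86e-3, "ci_y": 3.29e-3},
      {"x": 2.33e-1, "y": 9.42e-1, "ci_x": 1.67e-3, "ci_y": 1.05e-3}
    ]
  }
}
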