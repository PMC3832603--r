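{
  "channel": "green",
  "camera": "Canon 40D",
  "bit_depth": 8,
  "g_max": 250,
  "p_min": 31,
  "e_max_umol": 0.0125,
  "biexp": {
    "b": 85.5, "c": 4200, "d": 172, "g": 961,
    "ci_halfwidths": {"b": 21, "c": 1000, "d": 22, "g": 99},
    "scale": "original"
  },
  "bezier": {
    "control_points": [
      {"x": 1.21e-2, "y": 2.29e-1, "ci_x": 2.40e-4, "ci_y": 4.03e-3},
      {"x": 1.18e-2, "y": 3.02e-1, "ci_x": 5.15e-4, "ci_y": 6.00e-3},
      {"x": 4.68e-2, "y": 8.34e-1, "ci_x": 9.35e-4, "ci_y": 3.51e-3},
      {"x": 1.96e-1, "y": 9.40e-1, "ci_x": 5.61e-4, "ci_y": 5.44e-4}
    ]
  }
}
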