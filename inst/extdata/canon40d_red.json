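{
  "channel": "red",
  "camera": "Canon 40D",
  "bit_depth": 8,
  "g_max": 250,
  "p_min": 31,
  "e_max_umol": 0.0122,
  "biexp": {
    "b": 103, "c": 3640, "d": 157, "g": 981,
    "ci_halfwidths": {"b": 34, "c": 960, "d": 33, "g": 159},
    "scale": "original"
  },
  "bezier": {
    "control_points": [
      {"x": 1.09e-2, "y": 2.20e-1, "ci_x": 1.91e-4, "ci_y": 3.85e-3},
      {"x": 1.31e-2, "y": 2.73e-1, "ci_x": 5.19e-4, "ci_y": 6.10e-3},
      {"x": 2.74e-2, "y": 8.66e-1, "ci_x": 1.07e-3, "ci_y": 3.55e-3},
      {"x": 1.87e-2, "y": 9.62e-1, "ci_x": 1.30e-3, "ci_y": 1.09e-3}
    ]
  }
}
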