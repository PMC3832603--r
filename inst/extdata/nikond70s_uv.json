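{
  "channel": "uv",
  "camera": "Nikon D70s (UV-modified)",
  "bit_depth": 8,
  "g_max": 250,
  "p_min": 37,
  "e_max_umol": 0.0081,
  "biexp": {
    "b": 248, "c": 1540, "d": 12, "g": 14700,
    "ci_halfwidths": {"b": 16, "c": 20, "d": 13, "g": 27300},
    "scale": "original"
  },
  "bezier": {
    "control_points": [
      {"x": 2.02e-2, "y": 2.40e-1, "ci_x": 4.61e-4, "ci_y": 4.66e-3},
      {"x": 3.70e-2, "y": 3.21e-1, "ci_x": 1.51e-3, "ci_y": 7.34e-3},
      {"x": 7.04e-2, "y": 8.65e-1, "ci_x": 3.49e-3, "ci_y": 3.83e-3},
      {"x": 2.37e-1, "y": 9.58e-1, "ci_x": 3.20e-3, "ci_y": 2.52e-3}
    ]
  }
}
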