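{
  "scan_id": "example_scan",
  "lateral_scale_um_per_px": 11.6,
  "axial_scale_um_per_px": 3.87,
  "fovea_x": 99,
  "boundaries": {
    "ILM": [
      [0, 14],
      [60, 14],
      [99, 22],
      [138, 14],
      [199, 14]
    ],
    "RPE_inner": [
      [0, 54],
      [199, 54]
    ],
    "RPE_outer": [
      [0, 61],
      [199, 61]
    ],
    "CSJ": [
      [0, 131],
      [50, 135],
      [99, 138],
      [150, 134],
      [199, 131]
    ]
  }
}
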