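{
  "name": "flattened_head",
  "edits": {
    "groove_flattening_scale": 0.3
  },
  "predicted_displacement": "none",
  "predicted_mobility": "restricted-sagittal",
  "note": "uniformly flattened articular surface washes out groove relief"
}
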