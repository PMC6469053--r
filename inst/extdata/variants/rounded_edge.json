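{
  "name": "rounded_edge",
  "edits": {
    "head_radius_scale": 0.8
  },
  "predicted_displacement": "distal",
  "predicted_mobility": "increased-frontal",
  "note": "rounded distal edge with diminished radius of curvature"
}
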