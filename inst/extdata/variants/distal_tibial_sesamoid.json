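{
  "name": "distal_tibial_sesamoid",
  "edits": {
    "tibial_sesamoid_angle_delta": 10
  },
  "predicted_displacement": "lateral-proximal",
  "predicted_mobility": "none",
  "note": "normally positioned (more distal) tibial sesamoid obliques the trans-sesamoid axis"
}
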