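{
  "name": "proximal_sesamoids",
  "edits": {
    "sesamoid_angle_delta": -6.51986456528178
  },
  "predicted_displacement": "proximal",
  "predicted_mobility": "none",
  "note": "both sesamoids repositioned proximally along the articular arc (0.15 R of arc); groove engagement is pushed into end-range declination where it is truncated by terminal dorsiflexion"
}
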