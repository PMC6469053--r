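{
  "name": "short_metatarsal",
  "edits": [],
  "predicted_displacement": "none",
  "predicted_mobility": "reduced-frontal",
  "note": "short first metatarsal: mechanism is diminished ground reaction force (out of scope)"
}
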