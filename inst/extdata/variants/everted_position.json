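{
  "name": "everted_position",
  "edits": {
    "eversion_deg": 10
  },
  "predicted_displacement": "medial-plantar",
  "predicted_mobility": "none",
  "note": "everted metatarsal position (pronation, sesamoid excision, arch loss)"
}
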