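{
  "units": {
    "length": "mm",
    "area": "cm2"
  },
  "joints": {
    "left": [0, 5, 0],
    "right": [0, -5, 0]
  },
  "gape_reference_deg": 0,
  "muscles": [
    {
      "name": "mame_vertical",
      "group": "external_adductor",
      "side": "left",
      "origin": [10, 5, 20],
      "insertion": [10, 5, 0],
      "acsa": 0.5
    },
    {
      "name": "mame_vertical",
      "group": "external_adductor",
      "side": "right",
      "origin": [10, -5, 20],
      "insertion": [10, -5, 0],
      "acsa": 0.5
    }
  ],
  "bite_points": [
    {
      "label": "jaw_tip",
      "position": [40, 0, 0]
    }
  ]
}
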