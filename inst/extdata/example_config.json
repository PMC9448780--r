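{
  "parameters": { "n": 2 },
  "schedule": {
    "t_start": [0, 14],
    "t_end": [14, 21],
    "stiffness_kpa": [15, 4]
  },
  "protocol": { "label": "St14So7" }
}
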