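[
  {
    "name": "CORE-NMP",
    "v1_tail": "90:99",
    "v1_head": "35:55",
    "v2_tail": "90:99",
    "v2_head": "115:125"
  },
  {
    "name": "CORE-LID",
    "v1_tail": "115:125",
    "v1_head": "179:185",
    "v2_tail": "115:125",
    "v2_head": "125:153"
  }
]
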