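[
  {
    "id": "root",
    "acronym": "BRAIN",
    "parent": null,
    "is_summary_target": false,
    "major_division": null
  },
  {
    "id": "iso",
    "acronym": "ISO",
    "parent": "root",
    "is_summary_target": false,
    "major_division": "isocortex"
  },
  {
    "id": "thal",
    "acronym": "TH",
    "parent": "root",
    "is_summary_target": false,
    "major_division": "thalamus"
  },
  {
    "id": "str",
    "acronym": "STR",
    "parent": "root",
    "is_summary_target": false,
    "major_division": "striatum"
  },
  {
    "id": "MOs",
    "acronym": "MOs",
    "parent": "iso",
    "is_summary_target": true,
    "major_division": null
  },
  {
    "id": "SSp",
    "acronym": "SSp",
    "parent": "iso",
    "is_summary_target": true,
    "major_division": null
  },
  {
    "id": "VAL",
    "acronym": "VAL",
    "parent": "thal",
    "is_summary_target": true,
    "major_division": null
  },
  {
    "id": "PO",
    "acronym": "PO",
    "parent": "thal",
    "is_summary_target": true,
    "major_division": null
  },
  {
    "id": "CP",
    "acronym": "CP",
    "parent": "str",
    "is_summary_target": true,
    "major_division": null
  },
  {
    "id": "ACB",
    "acronym": "ACB",
    "parent": "str",
    "is_summary_target": true,
    "major_division": null
  }
]
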