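{
  "form_id": "mini",
  "groups": {
    "Anamnesis": [],
    "Report": []
  },
  "cdes": [
    {
      "id": "prior_mammo",
      "question": "Prior mammogram mentioned?",
      "categories": [
        "yes",
        "no"
      ],
      "group_path": [
        "Anamnesis"
      ]
    },
    {
      "id": "lesion",
      "question": "Lesion mentioned?",
      "categories": [
        "yes",
        "no"
      ],
      "group_path": [
        "Report"
      ]
    },
    {
      "id": "side",
      "question": "Which side is the lesion on?",
      "categories": [
        "left",
        "right",
        "both"
      ],
      "group_path": [
        "Report"
      ],
      "gate": {
        "parent": "lesion",
        "values": [
          "yes"
        ]
      }
    }
  ]
}
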