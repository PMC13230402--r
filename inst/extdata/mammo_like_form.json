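{
  "form_id": "mammo_like",
  "groups": {
    "Anamnesis": [
      "History",
      "Prior imaging"
    ],
    "Report": [
      "Composition",
      "Findings",
      "Assessment"
    ]
  },
  "cdes": [
    {
      "id": "fam_history",
      "question": "Family history of breast cancer?",
      "categories": [
        "yes",
        "no"
      ],
      "group_path": [
        "Anamnesis",
        "History"
      ]
    },
    {
      "id": "fam_degree",
      "question": "Degree of affected relative?",
      "categories": [
        "first",
        "second"
      ],
      "group_path": [
        "Anamnesis",
        "History"
      ],
      "gate": {
        "parent": "fam_history",
        "values": [
          "yes"
        ]
      }
    },
    {
      "id": "symptoms",
      "question": "Reported symptoms?",
      "categories": [
        "none",
        "pain",
        "lump"
      ],
      "group_path": [
        "Anamnesis",
        "History"
      ]
    },
    {
      "id": "prior_mammo",
      "question": "Prior mammogram mentioned?",
      "categories": [
        "yes",
        "no"
      ],
      "group_path": [
        "Anamnesis",
        "Prior imaging"
      ]
    },
    {
      "id": "prior_interval",
      "question": "Interval since prior mammogram?",
      "categories": [
        "recent",
        "old"
      ],
      "group_path": [
        "Anamnesis",
        "Prior imaging"
      ],
      "gate": {
        "parent": "prior_mammo",
        "values": [
          "yes"
        ]
      }
    },
    {
      "id": "density_left",
      "question": "Tissue density left?",
      "categories": [
        "low",
        "medium",
        "high"
      ],
      "group_path": [
        "Report",
        "Composition"
      ]
    },
    {
      "id": "density_right",
      "question": "Tissue density right?",
      "categories": [
        "low",
        "medium",
        "high"
      ],
      "group_path": [
        "Report",
        "Composition"
      ]
    },
    {
      "id": "lesion_present",
      "question": "Lesion present?",
      "categories": [
        "yes",
        "no"
      ],
      "group_path": [
        "Report",
        "Findings"
      ]
    },
    {
      "id": "lesion_count",
      "question": "Number of lesions?",
      "categories": [
        "one",
        "multiple"
      ],
      "group_path": [
        "Report",
        "Findings"
      ],
      "gate": {
        "parent": "lesion_present",
        "values": [
          "yes"
        ]
      }
    },
    {
      "id": "lesion_side",
      "question": "Side of the lesion?",
      "categories": [
        "left",
        "right",
        "both"
      ],
      "group_path": [
        "Report",
        "Findings"
      ],
      "gate": {
        "parent": "lesion_present",
        "values": [
          "yes"
        ]
      }
    },
    {
      "id": "lesion_shape",
      "question": "Shape of the lesion?",
      "categories": [
        "round",
        "oval",
        "irregular"
      ],
      "group_path": [
        "Report",
        "Findings"
      ],
      "gate": {
        "parent": "lesion_present",
        "values": [
          "yes"
        ]
      }
    },
    {
      "id": "lesion_margin",
      "question": "Margin of the lesion?",
      "categories": [
        "smooth",
        "spiculated"
      ],
      "group_path": [
        "Report",
        "Findings"
      ],
      "gate": {
        "parent": "lesion_present",
        "values": [
          "yes"
        ]
      }
    },
    {
      "id": "calcifications",
      "question": "Calcifications associated?",
      "categories": [
        "yes",
        "no"
      ],
      "group_path": [
        "Report",
        "Findings"
      ],
      "gate": {
        "parent": "lesion_present",
        "values": [
          "yes"
        ]
      }
    },
    {
      "id": "calc_pattern",
      "question": "Pattern of the calcifications?",
      "categories": [
        "clustered",
        "diffuse"
      ],
      "group_path": [
        "Report",
        "Findings"
      ],
      "gate": {
        "parent": "calcifications",
        "values": [
          "yes"
        ]
      }
    },
    {
      "id": "suspicion_left",
      "question": "Level of suspicion left?",
      "categories": [
        "low",
        "intermediate",
        "high"
      ],
      "group_path": [
        "Report",
        "Assessment"
      ]
    },
    {
      "id": "suspicion_right",
      "question": "Level of suspicion right?",
      "categories": [
        "low",
        "intermediate",
        "high"
      ],
      "group_path": [
        "Report",
        "Assessment"
      ]
    },
    {
      "id": "followup",
      "question": "Recommended follow-up?",
      "categories": [
        "routine",
        "short interval",
        "biopsy"
      ],
      "group_path": [
        "Report",
        "Assessment"
      ]
    },
    {
      "id": "comparison_done",
      "question": "Comparison with prior images performed?",
      "categories": [
        "yes",
        "no"
      ],
      "group_path": [
        "Report",
        "Assessment"
      ]
    },
    {
      "id": "report_complete",
      "question": "Report formally complete?",
      "categories": [
        "yes",
        "no"
      ],
      "group_path": [
        "Report",
        "Assessment"
      ]
    },
    {
      "id": "results_communicated",
      "question": "Results communicated to referrer?",
      "categories": [
        "yes",
        "no"
      ],
      "group_path": [
        "Report",
        "Assessment"
      ]
    }
  ]
}
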