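{
  "schema_version": "1",
  "comment": "Ten tES study montages. Currents are the 1 mA reference configuration. Conductivities are documentation-only metadata for the FEM simulations that produced reference E-fields; they are not used in any computation here.",
  "conductivity_s_per_m": {
    "white_matter": 0.126,
    "grey_matter": 0.276,
    "csf": 0.85,
    "bone": 0.01,
    "skin": 0.465,
    "air": 2.5e-14,
    "gel": 0.3,
    "electrode": 59000000.0
  },
  "montages": [
    {
      "montage_id": "F4-Cz",
      "class": "conventional",
      "description": "fronto-central",
      "anode": {"label": "F4", "current_ma": 1.0},
      "cathodes": [{"label": "Cz", "current_ma": -1.0}],
      "electrode_radius_mm": 28,
      "electrode_thickness_mm": 1
    },
    {
      "montage_id": "C3-FP2",
      "class": "conventional",
      "description": "centro-frontal",
      "anode": {"label": "C3", "current_ma": 1.0},
      "cathodes": [{"label": "FP2", "current_ma": -1.0}],
      "electrode_radius_mm": 28,
      "electrode_thickness_mm": 1
    },
    {
      "montage_id": "F3-F4",
      "class": "conventional",
      "description": "cross-hemisphere frontal",
      "anode": {"label": "F3", "current_ma": 1.0},
      "cathodes": [{"label": "F4", "current_ma": -1.0}],
      "electrode_radius_mm": 28,
      "electrode_thickness_mm": 1
    },
    {
      "montage_id": "P3-FP2",
      "class": "conventional",
      "description": "parietal-frontal",
      "anode": {"label": "P3", "current_ma": 1.0},
      "cathodes": [{"label": "FP2", "current_ma": -1.0}],
      "electrode_radius_mm": 28,
      "electrode_thickness_mm": 1
    },
    {
      "montage_id": "C3-C4",
      "class": "conventional",
      "description": "cross-hemisphere central",
      "anode": {"label": "C3", "current_ma": 1.0},
      "cathodes": [{"label": "C4", "current_ma": -1.0}],
      "electrode_radius_mm": 28,
      "electrode_thickness_mm": 1
    },
    {
      "montage_id": "FPz-Oz",
      "class": "conventional",
      "description": "midline fronto-occipital",
      "anode": {"label": "FPz", "current_ma": 1.0},
      "cathodes": [{"label": "Oz", "current_ma": -1.0}],
      "electrode_radius_mm": 28,
      "electrode_thickness_mm": 1
    },
    {
      "montage_id": "HD-F4",
      "class": "HD",
      "description": "frontal high-definition ring",
      "anode": {"label": "F4", "current_ma": 1.0},
      "cathodes": [
        {"label": "F2", "current_ma": -0.25},
        {"label": "AF4", "current_ma": -0.25},
        {"label": "F6", "current_ma": -0.25},
        {"label": "FC4", "current_ma": -0.25}
      ],
      "electrode_radius_mm": 10,
      "electrode_thickness_mm": 1
    },
    {
      "montage_id": "HD-C3",
      "class": "HD",
      "description": "central high-definition ring",
      "anode": {"label": "C3", "current_ma": 1.0},
      "cathodes": [
        {"label": "P3", "current_ma": -0.25},
        {"label": "Cz", "current_ma": -0.25},
        {"label": "T7", "current_ma": -0.25},
        {"label": "F3", "current_ma": -0.25}
      ],
      "electrode_radius_mm": 10,
      "electrode_thickness_mm": 1
    },
    {
      "montage_id": "HD-P3",
      "class": "HD",
      "description": "parietal high-definition ring",
      "anode": {"label": "P3", "current_ma": 1.0},
      "cathodes": [
        {"label": "P1", "current_ma": -0.25},
        {"label": "CP3", "current_ma": -0.25},
        {"label": "P5", "current_ma": -0.25},
        {"label": "PO3", "current_ma": -0.25}
      ],
      "electrode_radius_mm": 10,
      "electrode_thickness_mm": 1
    },
    {
      "montage_id": "HD-PO8",
      "class": "HD",
      "description": "parietal-occipital high-definition ring",
      "anode": {"label": "PO8", "current_ma": 1.0},
      "cathodes": [
        {"label": "P6", "current_ma": -0.25},
        {"label": "PO4", "current_ma": -0.25},
        {"label": "P10", "current_ma": -0.25},
        {"label": "O10", "current_ma": -0.25}
      ],
      "electrode_radius_mm": 10,
      "electrode_thickness_mm": 1
    }
  ]
}
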