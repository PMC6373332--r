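{
  "dominance": "RD",
  "global": {
    "max_pathline_length_mm": 250,
    "max_angle_deg": 120,
    "min_pathline_length_mm": 1.0,
    "weight_threshold": 0.4
  },
  "labels": {
    "pRCA": {"weight": 1.0, "length_min_mm": 15, "length_max_mm": 35, "parent": null,   "subtree": "RCA", "position_class": "proximal"},
    "mRCA": {"weight": 1.0, "length_min_mm": 15, "length_max_mm": 35, "parent": "pRCA", "subtree": "RCA", "position_class": "mid"},
    "dRCA": {"weight": 1.0, "length_min_mm": 15, "length_max_mm": 35, "parent": "mRCA", "subtree": "RCA", "position_class": "distal"},
    "RPDA": {"weight": 1.0, "length_min_mm": 12, "length_max_mm": 25, "parent": "dRCA", "subtree": "RCA", "position_class": "side"},
    "RPLB": {"weight": 0.6, "length_min_mm": 8,  "length_max_mm": 18, "parent": "dRCA", "subtree": "RCA", "position_class": "side"},
    "LM":   {"weight": 1.0, "length_min_mm": 5,  "length_max_mm": 15, "parent": null,   "subtree": "LAD", "position_class": "proximal"},
    "pLAD": {"weight": 1.0, "length_min_mm": 15, "length_max_mm": 30, "parent": "LM",   "subtree": "LAD", "position_class": "proximal"},
    "mLAD": {"weight": 1.0, "length_min_mm": 15, "length_max_mm": 35, "parent": "pLAD", "subtree": "LAD", "position_class": "mid"},
    "dLAD": {"weight": 1.0, "length_min_mm": 10, "length_max_mm": 30, "parent": "mLAD", "subtree": "LAD", "position_class": "distal"},
    "D1":   {"weight": 0.6, "length_min_mm": 10, "length_max_mm": 20, "parent": "pLAD", "subtree": "LAD", "position_class": "side"},
    "D2":   {"weight": 0.3, "length_min_mm": 8,  "length_max_mm": 15, "parent": "mLAD", "subtree": "LAD", "position_class": "side"},
    "pLCX": {"weight": 1.0, "length_min_mm": 12, "length_max_mm": 25, "parent": null,   "subtree": "LCX", "position_class": "proximal"},
    "dLCX": {"weight": 1.0, "length_min_mm": 15, "length_max_mm": 30, "parent": "pLCX", "subtree": "LCX", "position_class": "distal"},
    "OM1":  {"weight": 0.6, "length_min_mm": 8,  "length_max_mm": 14, "parent": "pLCX", "subtree": "LCX", "position_class": "side"},
    "OM2":  {"weight": 0.3, "length_min_mm": 8,  "length_max_mm": 14, "parent": "dLCX", "subtree": "LCX", "position_class": "side"}
  }
}
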