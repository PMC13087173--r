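{
  "comment": "Default regulatory reference tables for edible fish tissue. Limits (ml) in mg/kg; reference doses (rfd) in mg/kg-bw/day; ingestion rates in g/day; body weights in kg. Override by passing your own file of the same shape to ref_tables().",
  "limits": [
    {"element": "As", "authority": "Brazil",        "ml": 1.0},
    {"element": "As", "authority": "MERCOSUL",      "ml": 1.0},
    {"element": "As", "authority": "Chile",         "ml": 1.0},
    {"element": "As", "authority": "WHO_FAO_Codex", "ml": 0.5},
    {"element": "Cd", "authority": "Brazil",        "ml": 1.0},
    {"element": "Cd", "authority": "MERCOSUL",      "ml": 0.05},
    {"element": "Cd", "authority": "Chile",         "ml": 0.05},
    {"element": "Cd", "authority": "WHO_FAO_Codex", "ml": 0.5},
    {"element": "Cu", "authority": "Chile",         "ml": 10},
    {"element": "Se", "authority": "Chile",         "ml": 0.3},
    {"element": "Pb", "authority": "Brazil",        "ml": 2.0},
    {"element": "Pb", "authority": "MERCOSUL",      "ml": 0.3},
    {"element": "Pb", "authority": "Chile",         "ml": 2.0},
    {"element": "Pb", "authority": "FAO",           "ml": 0.2},
    {"element": "Pb", "authority": "WHO_FAO_Codex", "ml": 0.3},
    {"element": "Zn", "authority": "Chile",         "ml": 100}
  ],
  "rfds": [
    {"element": "Al", "rfd": 0.286, "source": "ANVISA",  "status": "active"},
    {"element": "As", "rfd": 0.003, "source": "FAO_WHO", "status": "revoked"},
    {"element": "Cr", "rfd": 0.045, "source": "ANVISA",  "status": "active"},
    {"element": "Ni", "rfd": 1.0,   "source": "ANVISA",  "status": "active"},
    {"element": "Fe", "rfd": 3.47,  "source": "ANVISA",  "status": "active"},
    {"element": "Mn", "rfd": 2.3,   "source": "ANVISA",  "status": "active"},
    {"element": "Cu", "rfd": 6.935, "source": "ANVISA",  "status": "active"},
    {"element": "Zn", "rfd": 23.5,  "source": "ANVISA",  "status": "active"}
  ],
  "scenarios": [
    {"name": "general", "ingestion_rate": 63,     "population": "general Brazilian population"},
    {"name": "amazon",  "ingestion_rate": 416.39, "population": "Amazon region high-consumption population"}
  ],
  "profiles": [
    {"label": "adult", "body_weight": 70},
    {"label": "child", "body_weight": 15}
  ],
  "rq_authority": [
    {"element": "As", "authority": "Brazil"},
    {"element": "Pb", "authority": "Brazil"},
    {"element": "Cu", "authority": "Chile"},
    {"element": "Se", "authority": "Chile"}
  ]
}
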