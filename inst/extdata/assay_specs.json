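{
  "comment": "Kinetic spectrophotometric kit specifications. conversion_factor converts mean delta-absorbance per minute to U/L; calibration is the kit linearity-verification line (slope, intercept, r), stored as QC metadata and not applied during conversion.",
  "specs": [
    {"enzyme": "AChE", "conversion_factor": 62000, "wavelength": 405,
     "detection_limit": 50,    "linearity_max": 20000,
     "calibration": {"slope": 1.0028, "intercept": -170.85, "r": 0.9964}},
    {"enzyme": "AST",  "conversion_factor": 1746,  "wavelength": 340,
     "detection_limit": 1.756, "linearity_max": 400,
     "calibration": {"slope": 0.9765, "intercept": 1.0283,  "r": 0.9999}},
    {"enzyme": "ALT",  "conversion_factor": 1746,  "wavelength": 340,
     "detection_limit": 0.998, "linearity_max": 400,
     "calibration": {"slope": 0.9693, "intercept": 1.33,    "r": 0.9995}},
    {"enzyme": "ALP",  "conversion_factor": 2757,  "wavelength": 405,
     "detection_limit": 3.08,  "linearity_max": 1500,
     "calibration": {"slope": 0.9979, "intercept": -0.486,  "r": 0.9996}}
  ]
}
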