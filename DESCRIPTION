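Package: ecotoxfish
Title: Bioaccumulation Indices and Human-Health Risk Screening for
    Elements in Fish
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for ecotoxicological screening of potentially toxic and
    essential elements measured in fish tissue: acid-digest concentration
    arithmetic, Fulton condition factor, bioconcentration factors with
    US-EPA classification, risk quotients and cumulative risk indices
    against multi-authority maximum permissible limits, estimated daily
    intake across consumption scenarios with reference-dose screening,
    kinetic enzyme-biomarker activity conversion (AChE, AST, ALT, ALP),
    exact Mann-Whitney site contrasts, and a seeded synthetic-data
    generator calibrated to a two-site field survey so the whole pipeline
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
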