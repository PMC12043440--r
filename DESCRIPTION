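Package: thermalscope
Title: Field Respirometry, Aerobic Scope and Thermal Vulnerability of Fishes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intermittent-flow respirometry and metabolic
    phenotyping of wild fish populations. Extracts oxygen-uptake rates
    (MO2) from raw oxygen-depletion traces with quality control, computes
    resting and maximum metabolic rates (RMR, MMR) and absolute and
    factorial aerobic scope (AAS, FAS), fits thermal performance curves
    (T_opt, T_pejus) and the FAS-temperature relationship (T_FAS3), fits
    biexponential post-exercise recovery kinetics and solves recovery
    times, and combines critical thermal maxima with habitat temperature
    records into climate-vulnerability indices (thermal safety margin,
    functional warming tolerance). Includes a seeded synthetic-data
    generator emulating diel-fluctuating stream temperature regimes so
    the whole pipeline can be exercised end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
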