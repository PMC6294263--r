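Package: cthazard
Title: Cardiac Hazard Scoring for Calcium-Transient Screens in hiPSC
    Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Converts well-level calcium-transient fluorescence recordings
    from spontaneously beating human induced pluripotent stem cell-derived
    cardiomyocytes (hiPSC-CMs) into concentration-dependent cardiac hazard
    labels. Extracts beat-level parameters (CTD90, beat rate, amplitude)
    and abnormal phenotypes (early-afterdepolarization-like events,
    fibrillation-like activity, beating arrest), normalizes 30-minute drug
    effects against baseline and in-plate vehicle (delta and delta-delta
    percent), derives no-effect and strong-effect cutoffs from Wilks
    nonparametric tolerance intervals, and scores each compound-
    concentration study with a weighted matrix into no / low / high /
    very-high hazard classes. A seeded plate simulator provides realistic
    synthetic datasets so the full pipeline is testable without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
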