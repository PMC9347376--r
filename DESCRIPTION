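Package: CapsidQuant
Title: RP-UPLC Quantification of Picornavirus Capsid Concentration and
    Empty/Full Ratio
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reverse-phase ultra-performance liquid chromatography
    (RP-UPLC) analysis of picornavirus virion proteins (VP0-VP4), built around
    the Coxsackievirus A21 capsid system. Provides chromatographic peak
    detection, integration and retention-time assignment; calibration-curve
    quantitation of total capsid concentration; the VP0/(VP2+VP4) peak-area
    surrogate for the empty/full capsid ratio; method-validation statistics
    (%RSD, linearity, dilutional linearity, spike-mixture accuracy); intact
    protein identification from electrospray mass spectra via charge-state
    deconvolution and combinatorial adduct assignment (myristoyl, sodium); and
    a seeded synthetic-data generator that emulates fluorescence chromatograms
    under capsid stoichiometry and multi-charge ESI envelopes, with ground
    truth exposed for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
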