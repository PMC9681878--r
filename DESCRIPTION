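Package: cannastab
Title: Untargeted Cannabinoid Identification and Degradation Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for untargeted annotation of cannabinoids in
    UHPLC-TIMS-TOF feature data and for monitoring cannabidiol (CBD)
    degradation in stored formulations. Provides exact-mass arithmetic and
    CHO formula enumeration, isotope-pattern simulation, a packaged
    39-compound phytocannabinoid reference library with a five-criterion
    matcher (retention time, exact mass, isotopic pattern, collisional
    cross section, MS2 fragmentation), rule-based classification of
    oxidation products via diagnostic fragment ions, in-source
    fragmentation artifact detection, internal-standard normalisation,
    LOQ gating, storage-condition trend statistics with an internal
    Mann-Kendall test, and a seeded synthetic-data generator emulating
    day-1 profiling and four-condition stability studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
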