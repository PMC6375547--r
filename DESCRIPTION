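Package: srmkit
Title: Rapid Development of Scheduled SRM/MRM Assays from Shotgun Proteomics Spectral Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for turning annotated shotgun-proteomics results into
    ready-to-run scheduled (dynamic) SRM/MRM methods. Builds spectral
    libraries from peptide-spectrum matches and MGF peak lists, selects
    assay-suitable proteotypic peptides and their most intense fragment
    ions, transfers retention times to arbitrary chromatographic gradients
    through an empirical iRT-style linear calibration anchored on landmark
    reference peptides, and emits concurrency-validated dynamic-MRM
    transition lists with dwell-time feasibility reports. A seeded
    simulator generates random proteomes, in-silico tryptic spectral
    libraries with hydrophobicity-driven retention times, and
    gradient-transfer experiments, so the entire pipeline can be exercised
    and benchmarked without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    Biostrings
Config/testthat/edition: 3
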