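Package: hemequil
Title: Monomer-Dimer Equilibria and Heme Coordination of Plant Hemoglobins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of non-symbiotic plant hemoglobin
    self-association and heme coordination. Estimates monomer-dimer
    dissociation constants from analytical size-exclusion chromatography
    via the Manning linearization (with per-injection dilution correction),
    performs column calibration and apparent molecular-mass estimation,
    native-PAGE Ferguson-plot mass estimation, pentacoordinate-fraction
    estimation from deoxy visible spectra by band ratio or two-endmember
    least-squares unmixing, and two-state thermal-melt fitting. Includes
    seeded synthetic-data generators (chromatograms, gel mobility tables,
    spectra, melt curves) with presets for ground-truth parameter-recovery
    studies, and a command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
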