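Package: ssindex
Title: Stenosis Susceptibility Index from Virtual Stenosis Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the stenosis susceptibility index (SSI), a site-specific
    hemodynamic biomarker for coronary plaque deposition risk. Virtual stenoses
    of graded severity are inserted at candidate sites of a patient-specific
    coronary segment tree, a reduced-order (0D) network solver with
    vessel-length-calibrated lumped-parameter outlet resistances computes
    fractional flow reserve (FFR) and maximum wall shear stress (WSSmax) at
    each severity, and the SSI is the magnitude of the slope of WSSmax against
    FFR across severities. Includes per-artery and global minimum-SSI site
    ranking, a clinical concordance reporter for PCI-site observations, a
    deterministic synthetic coronary tree generator, and an arterial inlet
    pressure waveform builder for pulsatile runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
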