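Package: synpcr
Title: Synergistic Digital-Analogue PCR Assay Design and Quantification
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calibration-free absolute quantification of nucleic-acid
    targets from a small number of non-identical partitions read on a
    standard real-time PCR instrument. Combines the binary (digital)
    outcome of each partition with its threshold-cycle (Ct) value in a
    Bayesian posterior over concentration, estimates the per-cycle
    amplification factor without reference samples, designs geometric
    (multivolume) compartment sequences for a requested precision and
    dynamic range, and verifies designs by grand-canonical Monte-Carlo
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
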