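Package: digiwell
Title: Digital Microwell qPCR Quantification and Single-Cell Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for digital real-time PCR (dqPCR) performed on
    2,500-microwell chips. Implements Poisson digital quantification from
    positive-partition counts with failed-well and primer-dimer corrections,
    serial-dilution standard-curve fitting with amplification-efficiency
    estimation and single-copy Cq anchoring, quantification of PCR inhibitor
    (heparin) effects including IC50 estimation from log-logistic inhibition
    curves, Poisson modelling of single-cell loading across the chip, and
    single-cell gene-expression profiling with geometric means and
    Kolmogorov-Smirnov distribution tests. A seedable synthetic-chip generator
    reproduces the statistical structure of instrument output (molecule
    partitioning, Cq noise, failed wells, primer-dimer false positives,
    per-well inhibition, cell loading, lognormal expression) so every stage
    of the pipeline can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
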