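Package: mavemap
Title: Scoring, Classification, and Clinical Calibration of Deep Mutational Scans of an Ion-Channel Subunit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing multiplexed assays of variant effect (MAVEs)
    on a small single-pass membrane protein, modelled on saturation-mutagenesis
    screens of the 129-residue cardiac potassium channel subunit KCNE1.
    The package enumerates the single-amino-acid variant space of an NNK
    mutagenesis library, links random barcodes to variants from subassembly
    reads, computes normalized cell-surface-expression scores from four-bin
    sort-seq counts and normalized functional scores from day-0/8/20 depletion
    counts, assigns variants to six effect categories using bootstrap
    confidence intervals against anchor-derived cutoffs, and calibrates the
    assay as ACMG/AMP PS3/BS3 evidence through the OddsPath likelihood-ratio
    framework. A fully seeded synthetic-data generator emulates the barcoded
    library, the FACS sort, and the fitness selection so that every stage of
    the pipeline can be exercised and validated without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
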