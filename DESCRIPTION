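Package: immunecfdna
Title: Immune Cell Type-Specific Cell-Free DNA Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring immune-cell-type-specific cell-free DNA
    (cfDNA) from targeted bisulfite amplicon sequencing. Discovers
    cell-type-specific hypomethylated CpG markers from a reference
    methylation atlas, interprets amplicon reads into per-marker
    fully-unmethylated-molecule fractions with bisulfite-conversion QC,
    converts fractions to genome equivalents per ml of plasma with
    spike-in derived calibration, and provides the cohort-level statistics
    used in longitudinal immune-cfDNA studies (balanced intra/inter
    individual coefficients of variation, baseline fold change,
    seroconversion-based responder classification, empirical ROC curves and
    nonparametric group tests). Includes simulators for methylation
    atlases, bisulfite amplicon reads from cell-type mixtures, and cohort
    scenarios so the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
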