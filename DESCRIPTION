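Package: avmeth
Title: Arterial Versus Venous Endothelial Methylome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for two-group differential DNA
    methylation analysis of Infinium-style methylation array data, built
    around the paired arterial-versus-venous endothelial cell design.
    Covers quality filtering of two-channel intensities, beta- and
    M-value computation, a simplified type-II-to-type-I quantile
    normalization, empirical-Bayes moderated t-statistics with
    Benjamini-Hochberg false discovery rate control, differentially
    methylated probe and region calling, integration of methylation
    differences with gene-expression log fold changes via quadrant
    ("starburst") classification, genomic-region attribution of probes,
    hierarchical clustering of variable probes, global-methylation
    summaries, and a synthetic-data generator with a planted-truth
    ledger so the whole pipeline can be exercised offline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
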