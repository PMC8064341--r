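Package: eigenSweeps
Title: EigenGWAS Selective-Sweep Scans for Structured Crop Diversity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for labelling selective sweeps that differentiate landrace
    from modern germplasm in structured crop diversity panels genotyped with
    biallelic (presence-absence and SNP) markers. The package covers marker
    quality control (minor-allele-frequency, missingness and duplicate-pattern
    filters), Nei gene-diversity decomposition and gene-flow estimation,
    linkage-disequilibrium decay by LOESS intercept on a genetic map,
    principal-coordinates ordination on the simple matching coefficient,
    a mixed-linear-model eigenvector association scan (PCA fixed effects plus
    kinship random effect with P3D variance components), clustering of
    significant associations into QTL hotspots, and a dual-allele frequency
    rule for labelling sweep markers. A Balding-Nichols panel simulator with
    planted sweep regions provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    vcfR,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
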