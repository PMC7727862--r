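Package: mirres
Title: miRNA Biomarker Screening for Radiation and Chemotherapy Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for associating small-RNA expression with
    treatment resistance in cancer cell-line panels and patient serum
    extracellular-vesicle sequencing. Computes clonogenic and apoptosis-assay
    survival fractions, converts OpenArray-style qPCR Ct matrices to relative
    levels with data-driven housekeeping-miRNA selection and geometric-mean
    normalization, screens miRNAs for association with a resistance axis
    (extremes t-test, cross-line Spearman consistency, Storey false-discovery
    estimation, treatment-uniqueness calls), performs TMM-normalized
    Mann-Whitney differential expression of serum small-EV counts with
    cell-line cross-referencing, and screens paired small-RNA/mRNA profiles
    for negatively correlated regulatory pairs with database-consensus
    filtering and permutation gene-set enrichment. Includes synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
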