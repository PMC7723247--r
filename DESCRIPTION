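Package: colonymap
Title: Mendelian Mapping and Validation of Recessive Traits in Closed Breeding Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the full desk-side analysis used to localize a fully
    penetrant autosomal recessive trait segregating in a closed breeding
    colony: zygosity-based variant filtering across affected and
    obligate-carrier animals, chi-square tests of genomic clustering of
    passing variants, exact parametric two-point LOD scores under a rare
    recessive model, rule-based diplotype reconstruction with progeny
    imputation and critical-interval delineation from recombinant
    boundaries, variant prioritization by allele frequency, CADD score and
    tissue expression, and expression-level validation statistics for
    nonsense-mediated decay (transcript reduction, allele-specific read
    bias), dual-contrast FDR-intersection differential expression, and
    cell-type composition shifts. A gene-drop colony simulator generates
    pedigrees, genotypes, amplicon marker panels and RNA-seq style count
    data with the statistical structure the pipeline assumes, so every
    stage is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
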