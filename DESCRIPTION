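Package: landgdm
Title: Landscape Genomic Dissimilarity Modelling with Synthetic Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for landscape-genomic analysis of biallelic SNP genotypes:
    locality-level diversity statistics (expected heterozygosity, nucleotide
    diversity, Weir-Cockerham F_ST), genomic relationship matrices with the
    Gower transformation to genetic distances, PCA and Mantel tests, windowed
    linkage-disequilibrium decay fitting under the Hill-Weir expectation, and
    generalized dissimilarity modelling (GDM) of isolation by distance and
    environment with monotone I-spline predictors, category-wise forward
    selection, permutation-based backward selection, locality jackknifing and
    locality cross-validation. Includes a spatially explicit genotype and
    environment simulator with known ground truth so the entire pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
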