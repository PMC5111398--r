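Package: mitoskim
Title: Mitogenomic Resequencing Profiles of Bulk Invertebrate Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identify and quantify species in bulk invertebrate samples by
    mapping shotgun reads onto a reference library of mitochondrial genomes
    under a strict full-length, 99 percent identity, reference-unique
    contract. Calls species from per-mitogenome read-coverage fractions,
    normalises read counts by achieved mitogenome length and mitonuclear
    ratio to estimate biomass frequencies, and runs the downstream analyses
    of a mitogenomic monitoring pipeline: confusion-matrix detection
    statistics, biomass-read regression by ordinary and exponential-variance
    generalised least squares, Jaccard/Ruzicka dissimilarities with NMDS
    ordination and symmetric Procrustes tests, and bias-corrected Chao2
    richness with Welch comparisons. Includes a seeded simulator that
    generates reference libraries, bulk-sample compositions and shotgun
    reads with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
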