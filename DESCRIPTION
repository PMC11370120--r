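Package: breedkit
Title: Breed Identification from Genome-Wide SNP and InDel Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for livestock breed identification from genome-wide
    SNP and InDel genotypes. Provides variant hard filtering and marker
    quality control, linkage-disequilibrium pruning, neighbor-joining
    mislabel screening, supervised-admixture estimation of genomic breed
    composition with a purebred screen, five breed-informative-marker
    detection strategies (Delta, pairwise Wright's FST, Rosenberg's
    informativeness for assignment, mutual information, random-forest
    importances) with intersection and union panel combiners, and
    KNN/SVM/random-forest classification integrated by a majority
    ensemble rule, evaluated by replicated stratified tenfold
    cross-validation. Includes a Balding-Nichols multi-breed genotype
    simulator so the full pipeline can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    class,
    e1071,
    ranger,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
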