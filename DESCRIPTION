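Package: breedcomp
Title: Genomic Breed Composition Prediction and Low-Density Panel Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for estimating the breed composition of purebred and
    crossbred cattle from SNP genotypes. Simulates multi-breed genotype
    datasets under the Balding-Nichols divergence model (including
    recombination-mosaic crossbreds), predicts per-animal breed proportions
    with a SNP-BLUP ridge regression and with a supervised admixture
    likelihood maximised by EM on the probability simplex, designs
    low-density SNP panels by seven marker-selection strategies (Fst, PCA
    weighting, SNP-BLUP effect variance, random forest importance, PLS-DA
    weighting, position-based medoids, random), and evaluates agreement of
    low-density predictions against full-panel gold-standard compositions.
    Reads and writes PLINK 1 binary genotype files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    cluster,
    ape,
    ranger,
    mixOmics,
    withr,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
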