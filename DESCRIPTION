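Package: PCAtruth
Title: Evaluating PCA Reliability with Ground-Truth Color Populations
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A test bench for principal component analysis as used in
    population genetics. Synthetic "color populations" -- points in the RGB
    unit cube plus Gaussian noise, standing in for SNP genotypes -- provide
    datasets whose true structure is known by construction, so the behaviour
    of PCA can be measured rather than interpreted. The package implements
    centered SVD-based PCA with held-out-sample projection on observed
    features, distance-distortion reports between the original and reduced
    spaces, k-means cluster-homogeneity scoring with k equal to the square
    root of the sample size, marker-window expansion with missingness and
    noise-marker injection, a case-control association experiment comparing
    scans with and without principal-component adjustment, readers for
    EIGENSTRAT and PLINK text genotypes, and a registry of ready-made
    experiment configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: DimensionReduction, PrincipalComponent, Clustering,
    PopulationGenetics, GenomeWideAssociation, Software
RoxygenNote: 7.3.3
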