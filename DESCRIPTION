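Package: locusdiv
Title: Population-Genetic Characterization of a Multi-Gene Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize population-based variation across a
    multi-gene genomic locus from diploid genotype data: per-functional-
    category variant summaries (SNP density, Watterson's normalized
    variant-site count, expected heterozygosity, minor allele frequency),
    Weir-Cockerham F_ST with permutation significance, hierarchical AMOVA,
    allele-frequency divergence between ancestral groups, linkage-
    disequilibrium r-squared and D-prime (phased counts or EM for unphased
    data), greedy tag-SNP binning, and surrogate-SNP discovery around index
    variants. Includes a Balding-Nichols structured-population genotype
    simulator with tunable differentiation, LD blocks, and category-specific
    allele-frequency spectra for validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
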