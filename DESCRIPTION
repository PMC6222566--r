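Package: aggscan
Title: Quantitation and Genetic Mapping of Protein-Aggregation Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying punctate protein aggregates (foci) in
    fluorescence micrographs of yeast and human cells, and for mapping
    quantitative trait loci that modify the aggregation phenotype in a
    two-parent haploid cross. Implements off-focus DIC cell detection with
    locally adaptive segmentation, high-pass spatial filtering for sub-2-um
    puncta, the percent-of-fluorescent-cells-with-foci statistic, marker
    quality control (LD pruning, missingness and allele-frequency filters),
    a single-marker regression linkage scan with permutation-based false
    discovery rates, variance-explained models, aggregate size-distribution
    statistics, and seeded synthetic-data generators (meiotic genotypes,
    additive QTL phenotypes, rendered micrograph pairs) with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
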