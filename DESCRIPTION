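Package: pericolor
Title: Kernel Pericarp Pigmentation Phenotyping and Genetic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for quantifying maize pericarp pigmentation
    from flatbed kernel-scan images and dissecting its inheritance in doubled
    haploid (DH) biparental populations. Segments kernels from RGB scans by
    trend-corrected thresholding, morphological cleaning and watershed
    splitting; locates tip/base/width landmarks on each kernel contour and
    samples an axial region that avoids the yellow endosperm cap and the
    kernel tip; converts mean region RGB to a hue phenotype with IQR-based
    quality control. Tests qualitative one- to three-locus epistatic
    segregation models by chi-square goodness of fit, estimates line BLUEs
    and Cullis generalized heritability from a mixed model, and runs a
    single-QTL Haley-Knott genome scan with hidden-Markov genotype
    probabilities, permutation thresholds, Bayesian credible intervals and
    shrunken allele effects. A synthetic-data module generates kernel scans
    with known per-kernel color and simulates DH populations so the whole
    pipeline is testable without the original images or genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    lme4,
    multcomp,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png
Config/testthat/edition: 3
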