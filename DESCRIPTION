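Package: sweepGF
Title: Generating-Function Analysis and Inference of Hard Selective Sweeps of Arbitrary Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytic description of genealogies at a neutral locus linked to a
    hard selective sweep that completed at an arbitrary time in the past. The
    joint distribution of genealogical branch lengths is represented by its
    generating function (the joint Laplace transform), built by recursion over
    coalescent histories with the sweep embedded as an instantaneous
    partitioning of lineages (star-like or marked-Yule approximation). From
    the generating function the package derives the distribution of the time
    to the most recent common ancestor, the expected site frequency spectrum,
    marginal i-Ton branch-length distributions, genealogical topology
    probabilities, and probabilities of blockwise mutation configurations
    (the blockwise site frequency spectrum). These feed a composite-likelihood
    framework to jointly estimate the scaled mutation rate, the sweep
    completion time, and the selection coefficient, with ROC-based power
    evaluation. Internal coalescent simulators (an exact sampler of the
    analytic model and a structured coalescent along the beneficial-allele
    frequency trajectory) provide validation and synthetic data, and phased,
    ancestral-polarized VCF data can be converted to blockwise configurations
    for inference on real sequence variation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
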