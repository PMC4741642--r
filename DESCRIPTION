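Package: clonalPair
Title: Clonality Assessment for Paired Tumors from Mutation Concordance,
    Mutational Spectra, and Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to decide whether two tumors from one patient are clonally
    related (one seeded the other) or arose independently. Implements
    somatic-mutation concordance testing (one-sided Fisher exact test on the
    shared/specific 2x2 table, computed in log space, with Benjamini-Hochberg
    control across patients), strand-collapsed 96-trinucleotide-context
    mutational spectra with hierarchical clustering, binomial rescue of
    under-sampled variants from a patient-level superset against a
    sequencing-error null, and an arm-level copy-number clonality likelihood
    ratio (LR2) with a reference-null p value. A synthetic paired-tumor cohort
    generator with known ground truth supports calibration and power studies
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    vcfR,
    ape,
    ggplot2,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'utils.R'
    'AllClasses.R'
    'spectra.R'
    'io.R'
    'simulate.R'
    'concordance.R'
    'rescue.R'
    'cnv.R'
    'pipeline.R'
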