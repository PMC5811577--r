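Package: oscmod
Title: Circadian Oscillations of Cytosine Modifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterization of circadian oscillations in DNA
    cytosine modification (5mC/5hmC) measured by targeted bisulfite and
    oxidative bisulfite sequencing. Implements beta-value computation from
    methylated/unmethylated read counts with coverage and outlier quality
    control, ANOVA-based selection of epigenetically variable cytosines,
    fixed-period harmonic (cosinor) regression with amplitude and acrophase
    estimation, permutation and PCA-based oscillation tests, 5hmC estimation
    by oxBS subtraction, circular acrophase-difference statistics, an
    mRNA-modification phase-shift scan, per-site epigenetic aging regression,
    and a circadian-aging association battery (Fisher exact tests, binomial
    enrichment, weighted correlations). A count-level synthetic data
    generator with exported ground truth supports calibration and recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
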