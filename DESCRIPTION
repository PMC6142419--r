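Package: mdaqc
Title: Quality Assessment of Single- and Sparse-Cell Whole-Genome-Amplified
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the reliability of variant calls from single-
    and sparse-cell multiple displacement amplification (MDA) followed by
    exome sequencing. Implements replicate allelic-mismatch classification
    and its decay with cell input, signal-to-noise ratio (mean over standard
    deviation) of heterozygous allele frequencies on copy-neutral
    chromosomes, genotype-likelihood concordance, short-tandem-repeat
    dropout scoring, and copy-number / loss-of-heterozygosity detection from
    allelic imbalance via mirrored allele frequencies, variant-neighborhood
    median filtering and Gaussian kernel density estimation with Silverman
    bandwidth. Includes a forward simulator of cell-count-dependent
    amplification bias and dropout that emulates a leukemia cell line with a
    complex karyotype, so every analysis can be exercised and calibrated
    without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    nortest,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
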