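Package: poolfreq
Title: Allele Frequency Estimation in Pooled DNA from SNP Array Fluorescence Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-SNP allele-B frequencies in DNA bulks (pooled
    individuals) from two-channel SNP-array fluorescence intensity ratios,
    using a two-step approach: per-bulk Student tests for allele fixation
    against homozygous reference-line intensity clusters, followed by a
    common logit-link calibration curve fitted on controlled pools with
    known allele frequencies. Includes the weighted-deviation SNP quality
    score and filtering, controlled-pool designs and calibration-SNP
    selection, cross-validation and mean-absolute-error accuracy machinery,
    exact Clopper-Pearson bounds for the individual-sampling error of bulk
    frequencies, Modified Roger's distances between populations, and a
    synthetic-data generator with a known signal model for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
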