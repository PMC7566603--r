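Package: scatterde
Title: Overlay-Based Differential Expression Calling from Scatter-Plot Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls differentially expressed genes from bulk or single-cell
    RNA-seq count matrices by overlaying between-condition expression scatter
    onto between-replicate scatter in log10-TPM space: a gene is differentially
    expressed when its between-condition point is not covered, at a working
    dot size, by any point of the replicate cloud in all four
    replicate-by-condition combinations. The dot size is calibrated against
    transcriptome-wide replicate expression noise (the squared coefficient of
    variation between samples). Includes TPM normalization, low-expression
    filtering by maximum-likelihood distribution fitting with AIC model
    selection, a 2D Gaussian kernel-density p-value for optional refinement,
    correlation and principal-component response trajectories, and a seeded
    synthetic count generator with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
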