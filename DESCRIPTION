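Package: clockccd
Title: Clock Correlation Distance for Inferring Circadian Clock Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the progression of the circadian clock in groups of
    transcriptome samples that lack time-of-day labels. The method compares
    the pattern of pairwise rank correlations among 12 core clock genes to a
    reference pattern built by fixed-effects meta-analysis on the Fisher-z
    scale, summarising the dissimilarity as the clock correlation distance
    (CCD, the Euclidean distance between correlation vectors). Statistical
    significance is assessed by resampling random gene sets (CCD) or by
    permuting condition labels (delta CCD between two conditions, e.g. tumor
    versus non-tumor), with exact one-sided permutation p-values. Includes
    descriptive co-expression strength and median-absolute-deviation
    variability metrics, a sinusoidal circadian transcriptome simulator for
    validation, delimited-text readers and writers, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
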