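Package: magicqtl
Title: Whole-Genome Multitrait and Multienvironment QTL Analysis for MAGIC Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Whole-genome average interval mapping for multiparent (MAGIC)
    populations with multiple traits or environments. All marker intervals
    enter a linear mixed model simultaneously as random founder-indexed QTL
    effects; putative QTL are chosen by forward selection using a
    chi-square-mixture likelihood-ratio test for the presence of QTL
    variance and a multivariate outlier statistic for location. Includes a
    four-way MAGIC population and phenotype simulator, a hidden Markov model
    for founder-origin probabilities, a REML engine for the required
    Kronecker variance structures with an exact dimension reduction to the
    number of lines, QTL-by-environment testing, and per-QTL summaries
    (founder effect sizes, significance probabilities, LOGP scores and
    percentage of genetic variance explained).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
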