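Package: sgumbel
Title: Studentized-Gumbel Significance Analysis for Local Alignment Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-wise error rate controlling significance analysis for
    protein database search based on the Studentized-Gumbel statistic.
    Tabulates the null distribution of the studentized database-wide optimal
    local alignment score by importance-sampled Monte Carlo, converts raw
    alignment scores into P-values via query shuffling, and provides a
    calibration harness that contrasts these P-values with classical
    Gumbel/Karlin-Altschul E-values. Includes a self-contained Smith-Waterman
    affine-gap scoring engine, NCBI substitution-matrix and FASTA input,
    an adapter for an external blastp executable, and generators for
    synthetic protein sequences and score samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
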