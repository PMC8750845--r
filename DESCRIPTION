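Package: chimeratrace
Title: Crossover Localization in Chimeric Genes from Long-Read Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the crossover region of a chimeric gene formed by
    unequal crossing-over between two highly similar paralogs (the flagship
    use case is the CYP11B1/CYP11B2 hybrid of glucocorticoid-remediable
    aldosteronism) from long-read amplicon sequencing. Builds a catalog of
    paralog-discriminating and ambiguous sites from a Smith-Waterman
    alignment of the paralog pair, genotypes every on-target read at those
    sites, accumulates per-site mismatch-rate profiles, estimates background
    (99th percentile of ambiguous-site rates) and foreground (mean of
    above-background discriminating rates) levels, localizes the crossover
    with a four-parameter logistic fit, labels the crossover interval with
    exon/intron annotation, and renders fusion plots. Includes a nanopore-like
    read simulator with ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    minpack.lm,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
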