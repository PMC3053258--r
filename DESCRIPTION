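Package: plantpin
Title: Plant-Parameterized Discovery and Scoring of miRNA Hairpins from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers candidate plant microRNA precursors from mapped small-RNA
    reads and scores them with a five-feature Bayesian log-odds model
    parameterized for plants: a modified-sigmoid log-odds of length-normalized
    minimum free energy, shuffling stability of the secondary structure, read
    signature consistency, positional nucleus conservation (positions 2-12),
    and star-read presence. Candidate hairpins are excised around read clusters
    (up to 300 nt), folded with a built-in deterministic reference folder or an
    external Vienna-compatible folder, and filtered by plant miRNA:miRNA*
    duplex constraints. Includes the estimation procedures behind the plant
    parameter set (Gumbel-minimum and modified-sigmoid fits on binned MFE
    log-odds, discrete frequency estimation with pseudo-counts, conservation
    profiling with 10-fold cross-validation, excision-length selection,
    two-sample Kolmogorov-Smirnov comparisons) and a seeded synthetic data
    generator producing planted stem-loops, Dicer-like read stacks, and
    conserved miRNA families for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    withr,
    generics,
    ggplot2,
    minpack.lm,
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
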