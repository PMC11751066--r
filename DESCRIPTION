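Package: tfconcord
Title: Transcription Factor Target Concordance Testing with Weighted
    Kendall's Tau
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate master-regulator transcription factors by
    testing whether a factor's highest-scoring promoter binding sites sit on
    genes that are coordinately up- or down-regulated. Promoters are scanned
    with position weight matrices under a log10 likelihood-ratio score
    (Jindex); differential-expression tables are collapsed to a signed raw
    score of differential expression (RDE) combining fold change and FDR;
    and the rank concordance between a factor's Jindex-ranked target set and
    the RDE-ranked transcriptome is measured with a weighted Kendall's tau,
    calibrated against its exact permutation null both asymptotically and by
    Monte Carlo. Includes a self-contained synthetic-data generator (random
    motifs, promoters with planted occurrences, expression tables with a
    known planted regulator) and sliding-window rank profiles for
    visualising individual hits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
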