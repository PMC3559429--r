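Package: waterfallseq
Title: Reference-Free Transcriptome Profiling via Iterative Cross-Species
    Read Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling the transcriptome of a species with no
    reference genome by mapping short RNA-seq reads against an ordered
    cascade of related-species transcriptomes ("waterfall" mapping),
    collapsing counts over homolog clusters, and testing two-condition
    differential expression with a negative-binomial exact test
    (median-of-ratios normalization, method-of-moments dispersions,
    Benjamini-Hochberg correction). Also provides consensus
    transmembrane-protein prediction (signal-peptide trimming plus a
    2-of-3 vote over three independent predictors), a candidate-gene
    filter cascade with cross-species exclusion, small assay
    quantification rules (calcium imaging, immunostaining, qPCR), and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
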