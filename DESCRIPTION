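Package: mcmbench
Title: Benchmarking Quantitative Microbial Profiling with a Synthetic
    Metagenomic Control Material
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico framework for assessing the precision and bias of
    quantitative microbial profiling methods against a defined metagenomic
    control material (MCM): a ten-species mock community with known genome
    sizes, 16S rRNA (rrn) gene copy numbers and absolute genome copy
    concentrations. The package simulates measurement of the community by
    16S rRNA amplicon sequencing under four primer strategies with
    mismatch-driven PCR bias, by whole-genome shotgun (WGS) paired-end
    sequencing, by microfluidic digital PCR (dPCR) with Poisson partition
    statistics, and by fluorometry. It implements high-stringency amplicon
    and WGS read filters with per-rule attrition accounting, shared k-mer
    scoring with top-score retention and lowest-common-ancestor taxonomic
    assignment, copy-number and genome-size abundance normalisation, and
    precision statistics: per-species percent coefficient of variation,
    bootstrap subsampling precision curves, and method-comparison tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
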