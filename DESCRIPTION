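Package: poolsel
Title: Divergence Islands and Selection Coefficients from Pooled
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of pooled whole-genome resequencing (pool-seq) data
    from marine and freshwater fish populations. Estimates per-pool allele
    frequencies from nucleotide count tables, classifies marine-freshwater
    marker SNPs under strong and weak frequency criteria, aggregates markers
    into divergence islands by windowed clustering with gap merging,
    computes nucleotide diversity inside and outside islands, classifies
    coding SNPs as synonymous or nonsynonymous against gene models and runs
    contingency comparisons, and estimates selection coefficients from
    allele-frequency change in populations of known age under deterministic
    diploid selection with dominance. A Wright-Fisher metapopulation
    simulator generates pooled count data with ground truth so the whole
    pipeline can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
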