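Package: apobecemt
Title: APOBEC3 Mutational Signatures and EMT Scoring in Paired Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying APOBEC3-driven mutagenesis from somatic
    single-nucleotide variants and relating it to tumor progression in paired
    primary/metastatic cohorts. Builds pyrimidine-normalized 96-channel
    trinucleotide mutation catalogs from VCF or variant tables, refits them
    to a reference signature set by non-negative least squares, extracts de
    novo signatures by Kullback-Leibler non-negative matrix factorization,
    attributes APOBEC-context mutations to APOBEC3A-like versus APOBEC3B-like
    activity from YTCA/RTCA tetranucleotide contexts, classifies samples as
    APOBEC-high or -low with paired metastatic enrichment and survival
    summaries, and computes expression-derived epithelial, hybrid-EMT and
    mesenchymal trajectory scores and IL6-correlated gene-category scores.
    A fully seeded synthetic-data generator produces every input the pipeline
    consumes: reference sequences, signature-mixture variant sets, paired
    cohorts with planted enrichment and survival structure, and
    negative-binomial expression matrices with planted gene-set shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
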