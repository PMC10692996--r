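Package: mutaccum
Title: Mutation-Accumulation Line Analysis of Germline Mutation Rates
Version: 0.1.0
Authors@R: person("mutaccum", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for mutation-accumulation (MA) line experiments in
    diploid organisms: forward simulation of an MA experiment with known
    ground truth, de novo single-nucleotide mutation calling by a
    consensus (unique-heterozygote) rule and by a probabilistic
    single-mutant-line posterior model, automated curation filters,
    callable-site accounting, per-site per-generation mutation rate
    estimation (mu = m/(L*n*T)), mutation-spectrum statistics with
    Monte-Carlo chi-squared tests, a minimal variant-effect predictor,
    regime-comparison generalized linear models, and a seeded end-to-end
    pipeline with standard-format (FASTA/VCF/BED/GFF3/TSV) entry points.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    optparse,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
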