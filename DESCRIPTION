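Package: oligodecomp
Title: Shannon-Entropy Oligotyping of Amplicon Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale reusable pipeline for strict amplicon community
    analysis: quality trimming and filtering of merged reads, length
    normalization into a positional matrix, de novo greedy OTU clustering at
    strict identity thresholds, best-hit taxonomic assignment against a
    labeled reference FASTA, and Shannon-entropy oligotype decomposition
    that separates haplotypes differing by as little as a single nucleotide
    from sequencing noise. Includes a synthetic amplicon-community generator
    emulating the structure of a Greenland ice-algal 18S survey, so every
    stage can be exercised and verified without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    BiocGenerics,
    IRanges,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'synth.R'
    'seqio.R'
    'preprocess.R'
    'otu.R'
    'taxonomy.R'
    'oligotype.R'
    'report.R'
    'RcppExports.R'
RoxygenNote: 7.3.3
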