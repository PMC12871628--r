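Package: kmerdict
Title: Order-Preserving Minimizer-Based k-mer Dictionaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An associative, order-preserving dictionary over the k-mers of a
    spectrum-preserving string set (SPSS). The index combines sparse hashing
    (a minimal perfect hash function over the minimizers of the input) with a
    skew index that resolves highly repetitive minimizers in a single probe,
    a cache-friendly three-type tag layout for locate sets, and Elias-Fano
    coded string offsets. It supports exact membership (LOOKUP) with handles
    in the minimal range [1..n], the inverse ACCESS query, and a budget-based
    streaming lookup over reads that reuses the previous match. Both a
    regular (single-strand) and a canonical (strand-agnostic) modality are
    provided, together with a synthetic SPSS/read generator, FASTA/FASTQ
    input, index serialization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    Biostrings,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
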