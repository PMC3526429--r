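Package: kmercompare
Title: Alignment-Free Comparison of Metagenomic Read Sets by Shared k-mers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two or more metagenomic read sets without alignment by
    finding, in each set, the reads that share at least t non-overlapping
    k-mers with the sequence content of the other set. Membership of k-mers
    is tested against a Bloom-filter variant that keeps one dedicated 2^k-bit
    array per hash function, where the hash functions are position-wise
    nucleotide-to-bit projections supporting O(1) rolling updates along a
    read. Includes an exact closed-form model of the index false-positive
    rate used for parameter selection, a symmetric three-pass comparison
    pipeline with a read-level similarity percentage, all-pairs sample
    comparison with hierarchical clustering output, and a deterministic
    synthetic-read generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
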