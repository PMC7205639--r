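Package: codonscape
Title: Codon Usage Similarity Between RNA Viruses and Host Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the synonymous codon usage of RNA virus coding
    sequences with that of individual host genes. Computes per-gene
    relative synonymous codon usage (RSCU), codon adaptation index (CAI),
    third-position G+C content (GC3) and a cell-cycle codon score (CCCS);
    ordinates the joint host/virus RSCU matrix by covariance-matrix
    principal components with quartimax rotation and a
    Kaiser-Meyer-Olkin adequacy check; selects host genes inside a
    fixed-radius disk around virus-subgroup centroids in component
    space; and tests annotation-term overrepresentation of the selected
    genes with the hypergeometric distribution. Includes a seeded
    synthetic-data generator so the whole analysis runs without sequence
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
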