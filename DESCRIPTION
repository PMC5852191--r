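Package: dnascape
Title: Graphical Classification of Same-Locus DNA Sequences with Stacked
    Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes labeled same-locus DNA sequences (for example HLA-A
    alleles) either as binary positional one-hot vectors or as overlapping
    k-mer document vectors, compresses the encoded matrix to two dimensions
    with a greedy layer-wise stacked autoencoder trained by plain stochastic
    gradient descent, and compares the resulting embedding against a PCA
    baseline.  Cluster separation of allele families in the 2-D plane is
    quantified with silhouette scores.  Includes a seeded synthetic
    allele-family generator so the whole pipeline is testable without
    external sequence databases, plus FASTA input, TSV/JSON output and
    ggplot2 scatter plots of the embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
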