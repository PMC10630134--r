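Package: chainani
Title: Fast, Fragmentation-Robust Average Nucleotide Identity by Sparse k-mer Chaining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates average nucleotide identity (ANI) and aligned fraction (AF)
    between genome assemblies by chaining sparse FracMinHash k-mer seeds into
    approximate orthologous alignments, making the estimate robust to the
    fragmentation, incompleteness and contamination typical of
    metagenome-assembled genomes. Includes a max-containment marker screen with
    an inverted index for database search, a bootstrap confidence interval over
    query chunks, an optional learned debiasing step, a synthetic-genome
    generator implementing an independent-substitution mutation model with
    assembly-quality degradation, and sketch/dist/triangle/search command-line
    style entry points.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    digest,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
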