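Package: complexmap
Title: Sliding-Window k-mer Complexity Profiling of Haplotype-Resolved
    Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Low-complexity mapping of genome assemblies: per-window k-mer
    diversity (distinct k-mers over total k-mers) computed on a sliding-window
    grid at several k scales, segmentation of low-complexity windows into
    repetitive blocks with terminal classification, per-chromosome repetitive
    content ranking, window-matched comparison of two haplotype assemblies
    with classification of conserved versus haplotype-specific low-complexity
    regions, and telomere motif scanning at chromosome termini. Includes a
    reproducible synthetic diploid genome generator that plants telomeric
    arrays, tandem repetitive blocks, dispersed repeat families, inversions
    and reciprocal translocations together with machine-readable ground
    truth, so every stage of the pipeline can be validated against planted
    features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
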