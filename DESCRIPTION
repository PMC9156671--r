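Package: pansv
Title: Structural-Variant Analysis of Minigraph-Style Pangenome Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing structural variation in reference-backed
    (rGFA) pangenome graphs of the kind produced by iterative assembly-to-graph
    construction. Detects superbubbles and types them as insertions, deletions
    or complex sites; retraces per-assembly haplotype walks into a bubble-by-
    assembly allele matrix; builds UPGMA dendrograms from pairwise bubble
    discordance and classifies their topology; scores agreement between SV
    sets from replicate pangenomes (precision/recall/F1, shared fractions);
    tests coding-sequence overlap depletion with a uniform permutation null
    and a one-sided Wilcoxon signed-rank test; annotates coding consequences
    of SVs including in-frame tandem-repeat expansions and depth-based copy
    number; and computes assembly-completeness metrics (NG50, PG50, QV,
    telomere/satellite completeness, coverage dropouts). A planted-truth
    pangenome simulator generates graphs, walks, annotation and depth tracks
    with known SV catalogues so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    optparse
Config/testthat/edition: 3
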