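Package: degenphy
Title: Codon Degeneracy Recoding and Compositional Heterogeneity
    Diagnostics for Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for separating synonymous from nonsynonymous signal in
    protein-coding nucleotide alignments and for diagnosing the
    compositional artifacts that synonymous change can introduce into
    phylogenetic estimates. Implements degen1 codon recoding (all codons
    of one amino acid collapse to a single IUPAC-degenerate
    representation, erasing synonymous signal), the complementary
    noLRall1nt2/LRall1nt3 character-set partition, Euclidean
    base-composition distance trees with bootstrap support for detecting
    compositional heterogeneity, heuristic-search adequacy statistics
    (search-effort estimates, lnL-threshold consensus subsets,
    best-of-k bootstrap convergence), strict, majority-rule and Adams
    consensus trees, rogue-taxon screening, and seeded simulators of
    codon alignments with lineage-specific GC3 bias for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
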