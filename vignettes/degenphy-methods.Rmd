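---
title: "Separating synonymous from nonsynonymous signal: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating synonymous from nonsynonymous signal: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degenphy)
library(dplyr)
```

## The problem

In deep-level phylogenetics of protein-coding genes, synonymous substitutions
accumulate much faster than nonsynonymous ones. At Mesozoic depths they
saturate: multiple overlapping changes erase most of their historical signal.
Worse, lineages can drift in base composition — typically in GC content at
synonymously free positions (GC3) — and two unrelated lineages that drift the
same way come to *look* similar at those positions. Distance and likelihood
methods then pull such lineages together with high confidence. The artifact
is insidious precisely because it produces *strong* support for a wrong
grouping.

`degenphy` packages the machinery for dealing with this:

1. **degen1 recoding** removes synonymous signal while preserving
   nonsynonymous signal;
2. **character-set partitioning** (noLRall1nt2 / LRall1nt3) separates the two
   signal classes for partitioned analyses;
3. **composition diagnostics** quantify and visualize compositional
   heterogeneity via Euclidean composition-distance trees and a composition
   bootstrap;
4. **tree-set statistics** measure how hard a heuristic search problem is
   (search-effort estimates, lnL-threshold consensus, best-of-k bootstrap
   convergence) and screen for rogue taxa;
5. **simulators** generate codon alignments in which the synonymous and
   nonsynonymous layers are separable *by construction*, so every claim above
   is testable end to end.

## degen1 recoding

Every sense codon is mapped to the fully degenerate IUPAC representation of
its amino-acid family: `CAT` and `CAC` (His) both become `CAY`; all four Ala
codons become `GCN`. Two families are deliberately merged because their codon
sets are connected by single synonymous-like changes at the first position:
Leu (`TTR` + `CTN`) degenerates to `YTN`, whose resolutions also include the
Phe codons, and Arg (`AGR` + `CGN`) to `MGN`, which also covers Ser2. Phe and
Ser2 themselves keep `TTY` and `AGY`. Serine's two blocks (`TCN` vs `AGY`)
are never merged: their joint degeneracy pattern would also match stop and
foreign-family codons.

```{r degen-table}
tbl <- build_degen_table()
tidy(tbl) |> filter(amino_acid %in% c("L", "F", "S", "R")) |> count(amino_acid, image)
```

The construction is generic over a translation table (any identifier accepted
by `Biostrings::getGeneticCode()`): codons of one amino acid sharing their
first two positions collapse to a third-position union, and multi-block
families merge only when the merged pattern matches no stop codon and covers
every block it touches in full. For the standard code this reproduces the
published degen1 mapping exactly; the test suite verifies all synonymous
codon pairs exhaustively.

**Ambiguous codons.** An ambiguous codon maps to the shared degen1 image of
its sense resolutions when that image is unique. When resolutions span a
merged family (the codon `YTN` itself resolves to Leu and Phe codons with
images `YTN` and `TTY`), the position-wise union of those images is used if
it is itself a family image; otherwise the codon becomes `NNN`. This keeps
the mapping idempotent over the entire IUPAC alphabet — re-running degen1 on
recoded data is a no-op — which the tests check over all 15³ codons.

**Stop codons.** Real ORFs should not contain internal stops, so their
treatment is a policy, not a hidden default: `to_missing` (default; recode
as `NNN` with a warning), `passthrough`, or `error`. `validate_frame()`
reports internal stops and frame anomalies per taxon before recoding.

**Column classification.** `classify_columns()` assigns every third codon
position, plus the first positions of Leu/Arg codons (where first-position
change can be synonymous), to the mostly-synonymous set `LRall1nt3`; all
second positions and remaining first positions form the nonsynonymous-only
set `noLRall1nt2`. A first-position column joins the Leu/Arg set under the
`any_taxon` rule (default) when any taxon's codon there is unambiguously
Leu/Arg — ambiguity-tolerant in the sense that an ambiguous codon counts only
if *all* its sense resolutions are Leu or Arg; `all_taxa` is available for
sensitivity analysis. The two sets are disjoint and exhaustive over in-frame,
non-masked columns. Coordinates are 1-based inclusive throughout, matching
both R indexing and the NEXUS SETS convention in which they are written.

## Composition diagnostics

For each taxon the proportions of A, C, G, T are computed over its whole
(concatenated) sequence; by default only unambiguous bases count
(`ambiguity_rule = "exclude"`), because degen1 matrices are rich in Y/R/M/N
codes whose fractional attribution is a modeling choice, not an observation.
A `fractional` mode (each code contributes equal weight to its compatible
bases) is provided for sensitivity analysis.

Pairwise Euclidean distances between these 4-vectors (unitless,
"per cent / 100"; bounded by √2) feed a neighbor-joining tree, optionally
refined by ordinary-least-squares minimum evolution with nearest-neighbor
interchange (NNI) hill climbing. Branch lengths of this tree reflect
*composition alone*; its total length is the package's heterogeneity
statistic — the longer the composition tree, the more heterogeneous the
taxon set. A column bootstrap (`composition_bootstrap()`) resamples
alignment columns, rebuilds the composition tree per pseudoreplicate, and
maps majority-rule split frequencies onto the full-data tree, so that
distinct compositional similarity between particular taxa (beyond long
subtending branches) becomes visible as support.

Numerical conventions, chosen once:

* **NJ tie-breaking**: taxa are sorted into canonical label order before
  agglomeration, so outputs are deterministic and independent of input
  order.
* **Negative branch lengths**: NJ clamps negatives to zero (deficit recorded
  in an attribute); ME refinement keeps raw OLS values on the tree while
  `tree_length()` clamps when reporting. OLS fits use the unconstrained
  least-squares solution on the path-indicator design matrix.
* **Rooting for display**: midpoint, as an objective stand-in for the
  subjective "minimize groups branching off a central backbone" layout
  criterion used in published composition diagrams.
* **Outlier flagging** (`flag_heterogeneous_taxa()`): `centroid_z` scores
  each taxon's distance to the mean composition against the
  leave-one-out mean and standard deviation of the remaining taxa — without the
  leave-one-out form a single extreme taxon among *n* can never exceed
  z ≈ (n−1)/√n and would mask itself; `tree_tail` flags the k longest
  root-to-tip paths on the midpoint-rooted composition tree, mirroring the
  practice of trimming taxa from both ends of the composition tree. The
  published boundaries were "largely arbitrary"; both rules are explicit
  parameters here.

## Tree-set statistics

**Search effort.** With per-replicate recovery probability *p*, the number
of independent heuristic searches needed to recover a target topology with
confidence *c* is n = ln(1−c)/ln(1−p). `replicates_needed()` rounds to the
*nearest* integer (minimum 1) rather than taking the ceiling: applied to the
published replicate counts (1827 and 19 of 4608 within 10⁻²% and 10⁻³% of
the best lnL) this reproduces the printed values 6 and 725, where ceiling
would give 6 and 726. `within_threshold_set()` interprets thresholds as
relative lnL gaps — a published "within 10⁻⁴ %" is `rel_threshold = 1e-6` —
and `hard_to_recover_nodes()` classifies each edge of the best tree by
whether it survives the strict consensus of tighter and tighter threshold
sets.

**Bootstrap convergence.** When each bootstrap pseudoreplicate is analyzed
with k heuristic search replicates, too small a k yields systematically
depressed support for hard-to-find groups. `best_of_k_supports()` selects,
per pseudoreplicate, the best-scoring tree among the first k replicates
(ties broken by generation order) and tabulates support as a function of k;
`convergence_report()` flags edges whose support at small k sits ≥ δ points
(default 5) away from the largest-k value. The generative model in
`sim_bootstrap_run()` — a latent per-pseudoreplicate best topology found by
each search with probability `q_find` — reproduces the direction of this
effect: support converges upward with k.

**Consensus trees.** Strict and majority-rule consensus are computed from
canonical bipartition sets (the frozen side not containing the reference
leaf); Adams consensus is the classical recursive partition-product on
rooted trees. Adams requires a root; inputs are rooted at a user-named
outgroup leaf (default: the first tip), a convention the user can change.
Majority support values are reported in percent, rounded only for display.

**Rogue screening.** Two complementary screens: `annotation_rogues()` flags
(a) members of multi-exemplar groups that sit in no clade composed chiefly
of their own group, and (b) sole exemplars attached at polytomies of degree
above a limit; `greedy_rbic_prune()` maximizes the relative bipartition
information criterion — the sum of majority-rule split supports divided by
the maximum attainable, `(n−3)·100` — by greedily dropping one taxon at a
time. This is a deliberate simplification of the RogueNaRok procedure
(single-taxon drops, majority-rule consensus, no dropsets); exact parity
with that tool is out of scope.

## The simulator and what it does (not) show

`sim_codon_alignment()` uses a two-layer model rather than a full codon
CTMC. The amino-acid layer is a Poisson process with uniform
exchangeabilities at rate `nonsyn_rate` per site per unit branch length.
Conditional on the amino acid, the codon is resampled at rate `syn_rate`
from the lineage's codon-usage profile; lineages in `biased_taxa` weight
each codon by `gc3_weight^(number of G/C at its degenerate positions)`,
where "degenerate" is defined by the degen1 image — the same table that the
recoder uses, so the two layers are separable by construction: the degen1
image of every site depends only on the amino-acid layer (serine's two
blocks being the one documented exception). This is exactly the property
that makes the simulator useful for testing; a GY94-style codon model would
entangle the layers and prove nothing extra here.

Default study conditions, chosen once and used by both the test suite and
the acceptance script: 16 taxa on a Yule tree (birth rate 1, mean depth
≈ 2.8), 500 codons, `nonsyn_rate = 0.05`, `syn_rate = 10`, two non-sister
GC3-biased lineages with `gc3_weight = 10`. The rate ratio makes synonymous
positions fully exchanged across the tree (saturated, as they are at deep
divergences in conserved nuclear genes) while nonsynonymous divergence stays
in the informative 5–15% range; γ = 10 drives biased lineages to GC3 ≈ 0.9
against ≈ 0.5 background, the "highly and similarly biased" regime in which
compositional attraction is known to mislead. The biased lineages are chosen
as the two longest-terminal-branch, non-sister tips
(`pick_nonsister_pair()`): isolated terminal lineages are exactly the taxa
for which shared bias is most misleading.

Under these conditions (`artifact_experiment()`, 100 seeds):

* NJ on raw (nt123) p-distances unites the two biased taxa in the majority
  of runs, while NJ on degen1 p-distances essentially never does;
* degen1 recovers the true generating topology in a strictly greater
  fraction of runs than nt123;
* the degen1 composition tree is shorter than the nt123 one in ≥95 of 100
  runs;
* the composition bootstrap unites the biased pair with ≈100% support under
  nt123 and single-digit support under degen1 in the median run.

What passing these tests does *not* show: the simulator has no indels, no
alignment error or mask, no rate heterogeneity across sites or time, no
realistic amino-acid exchangeabilities, and its compositional bias is a
stationary per-lineage codon-usage pull rather than an evolving drift. The
artifact reproduction is a qualitative twin of the published
compositional-attraction finding, not a quantitative reconstruction of any
published support value; real-data heterogeneity is both weaker per site
and aggregated over far more sites.

`sim_search_replicates()` and `sim_bootstrap_run()` are deliberately minimal
Bernoulli/latent-topology generators: they validate the search-effort
arithmetic and the best-of-k convergence direction, nothing more.

## Problem sizes and reproducibility

All stochastic entry points take a `seed` and restore the RNG state on exit;
identical seeds give bitwise-identical outputs, and the test suite checks
order-invariance of bootstrap supports under taxon permutation. The test
suite and `scripts/acceptance.R` use 100 artifact runs (16 taxa × 500
codons, 200 bootstrap pseudoreplicates per data set per run) and 200
simulated bootstrap runs (100 pseudoreplicates × 15 search replicates,
8 taxa); these sizes give stable rates (binomial SE ≤ 5 percentage points on
any reported rate) while keeping a full run in the low minutes on one core.
The composition bootstrap default of 500 pseudoreplicates matches standard
practice — at that size the binomial standard error of any support value
≥60% is at most ≈2.2 percentage points, comfortably inside the conventional
5-point reading accuracy.

## Known limitations

* Only column-level Leu/Arg classification is implemented for the character
  partition (`any_taxon` / `all_taxa`); per-cell (taxon × site) masking is a
  conceivable refinement that no published definition pins down.
* Adams consensus output is rooted at the chosen outgroup; different
  outgroups can yield different (all correct) Adams trees.
* The RBIC pruner is greedy and single-taxon; it can stop at a local
  optimum where a pair-drop would still help.
* NEXUS support covers the simple DATA/CHARACTERS + SETS dialect used for
  distributed supermatrices (interleaving, bracket comments, quoted names,
  charset strides); it is not a general-purpose NEXUS engine.
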