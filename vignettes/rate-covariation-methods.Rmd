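---
title: "Detecting co-evolving genes from rate covariation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting co-evolving genes from rate covariation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratecov)
```

## The statistic

Two genes whose products work together — members of one complex, one
operon, one pathway — experience coordinated shifts in selective pressure
across lineages, and those shifts leave a common imprint on their
substitution rates. `ratecov` detects this signal by correlating
*relative* branch-specific rates between gene phylogenies whose
topologies are constrained to a common species tree.

For a pair of gene trees and a reference species tree the procedure is:

1. **Prune** all three trees to the taxa shared by the pair (at least 4).
2. **Normalize**: divide each gene branch length by the corresponding
   reference branch length. Branch correspondence is by *bipartition* of
   the current taxon set, which is exact here because every gene tree is
   topology-constrained to the reference. Normalization removes the
   lineage effects shared by all genes (divergence time, genome-wide
   mutation rate), leaving each branch's relative rate, centered around 1.
3. **Filter outliers**: any branch whose normalized length exceeds 5 in
   *either* gene is removed from *both* vectors (paired deletion keeps the
   vectors aligned). Such branches are dominated by single-gene events —
   misalignment, hidden paralogy, horizontal transfer — rather than shared
   rate variation.
4. **Z-transform** each vector (sample SD) and compute Pearson's
   correlation `r` with the exact two-sided t-transform p-value on
   `n_branches − 2` degrees of freedom.
5. A pair is called **co-evolving** when `r > 0` and `p · m ≤ α`, where
   `m` is the Bonferroni family size: the number of *attempted*
   comparisons in the scan, including pairs skipped for insufficient data.
   Negative correlations are never called, whatever their p-value.

Reference genes are themselves screened by **quartet congruence**: the
fraction of 4-taxon subsets whose induced unrooted topology agrees
between the gene tree and the species tree, enumerated exhaustively over
all `C(n, 4)` subsets. Genes with score strictly above 0.8 qualify. The
enumeration is intended for desk-scale taxon counts (tens of taxa); the
per-split vectorized scan keeps even `n = 60` (about half a million
quartets) tractable.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `outlier_threshold` | 5 | normalized-length cutoff (dimensionless ratio) |
| `alpha` | 0.05 | family-wise level after Bonferroni |
| `min_overlap` | 10 | minimum aligned branches per pair; keeps ≥ 8 df for the t-transform, so the p-value is not driven by 3–4 points |
| quartet `cutoff` | 0.8 | strict congruence threshold for reference genes |
| `min_ref_links` | 5 | candidate screen: reference genes a family must co-evolve with, and rank highly against |
| `percentile` | 95 | candidate screen: strict rank-percentile cutoff, per reference gene, required in *both* the ascending-p and descending-r rankings |
| co-fitness `hi`/`lo` | 0.75 / 0.60 | edge rule: score > 0.75, or > 0.60 and conserved across species (both strict) |
| `n_perm` | 1000 | permutations for the network nulls |

## Network comparison

Co-evolution calls are assembled into an undirected network (nodes =
genes, edges = significant pairs, isolated nodes retained) and compared
against independent functional structure:

- **Edge Jaccard index** against an interaction or co-fitness network,
  after restricting both networks to their common node set — interaction
  databases cover only part of any gene universe, and edge overlap across
  mismatched universes is meaningless. The null replaces the co-evolution
  edge set with a uniform random edge set *of the same size* over the same
  nodes. A degree-preserving double-edge-swap null is available behind
  `method = "degree"` for sensitivity analysis; the size-preserving
  uniform shuffle is the default because it is the weakest assumption
  consistent with "edges randomly shuffled", and because the co-evolution
  degree sequence is itself part of the signal being tested.
- **Nominal assortativity** over categorical (e.g. COG-style) labels,
  computed from the edge mixing matrix:
  `r = (Σᵢ eᵢᵢ − Σᵢ aᵢbᵢ) / (1 − Σᵢ aᵢbᵢ)`, +1 when only same-class
  nodes connect, negative down to −1 in the fully disassortative case.
  The null shuffles labels over nodes, preserving the label multiset.

Both permutation p-values use the add-one rule
`p = (1 + #{null ≥ observed}) / (1 + n_perm)`, so with 1,000 permutations
the smallest reportable value is just under 0.001 and an exact zero is
never reported.

A subtlety worth knowing: for a network whose labels are assigned
independently of its edges, the *expected* assortativity is not 0 but
`−1/(n−1)` for `n` labeled nodes in balanced two-class settings, because
labels are drawn without replacement. The permutation null absorbs this
finite-size offset automatically; comparing the observed coefficient
against 0 at small `n` would not.

## Candidate screening and enrichment

A gene family is a candidate partner of the reference-gene set when it
(i) co-evolves (Bonferroni-significant, `r > 0`) with at least
`min_ref_links` reference genes and (ii) for at least `min_ref_links`
reference genes sits above the 95th percentile of all families scanned
against that reference gene in both rankings — ascending p *and*
descending r, read conjunctively and required to hold for the same
reference gene. Percentile positions use average ranks for ties, so large
blocks of numerically identical p-values (common at double-precision
zero) cannot inflate the passing set; families skipped for insufficient
data rank below all computed ones.

Within- vs between-module contrast on the reference genes uses a
two-sided Wilcoxon rank-sum test on the two sets of `r` values. The
implementation delegates to `stats::wilcox.test`, which is exact for
small tie-free samples and uses the tie-corrected normal approximation
otherwise.

Pathway enrichment of the candidate set is the classical upper-tail
hypergeometric test per pathway — `P(X ≥ k)` for `k` candidate members of
a `K`-gene pathway, `n` candidates, `N` universe genes — with Bonferroni
correction over the tested pathways.

## What the synthetic data emulates

`simulate_gene_trees()` plants rate covariation in a controlled way. On a
Yule reference tree with i.i.d. exponential branch lengths (mean 0.1
substitutions/site, a typical scale for single-copy bacterial families
across an order-level phylogeny), gene *i* in group *g* receives branch
lengths

```
l_ie = s_i · b_e · max(ε, 1 + σ·d_ie),   d_ie = √ρ_g · z_ge + √(1−ρ_g) · η_ie
```

with `z_ge` shared within the group, `η_ie` independent, both standard
normal, and `ε = 10⁻⁶` a positivity floor. The square-root mixing makes
`corr(d_i, d_j) = ρ` *exactly* for same-group genes, so ρ is a direct,
interpretable recovery target. The multiplicative truncated-normal form
(rather than log-normal) keeps normalized branch lengths centered at 1,
matching what the normalization step produces on real data. The per-gene
scale `s_i ~ Uniform(0.5, 2)` reflects the ~4-fold spread in average
rates typical among conserved single-copy families; the Z-transform must
(and, by the invariance test, does) remove it. Taxon dropout, independent
per gene, emulates families present in only part of the genome set;
`filter_by_prevalence()` re-applies a ≥ 50% presence criterion.

What the generator deliberately does **not** model: topology discordance
among gene trees (transfers, hidden paralogy), sequence-level noise in
branch-length estimation, among-site rate variation, and non-independent
taxon missingness. Passing the recovery tests therefore demonstrates the
statistical machinery is correct and calibrated under the stated model —
not that the method is robust to phylogenetic error in real data, which
is exactly why the upstream analysis constrains gene-tree topologies and
filters genes by quartet congruence before trusting their rates.

## Numerical and design choices

- **Unrooted branch set.** All rate computation uses the unrooted view of
  each tree; the two root-adjacent branches of a rooted input describe
  the same bipartition and are merged with lengths summed. Root placement
  on real data is a presentation choice, and keeping the rooted view
  would split one biological branch into two arbitrary pieces. (Whether
  the original rate-covariation tooling operates on the rooted or
  unrooted branch set is not documented; this package standardizes on
  unrooted.)
- **Paired outlier deletion.** The > 5 filter removes a branch from both
  members of the pair — the correlation needs aligned vectors — rather
  than from the offending gene only. This is an interpretation; the
  alternative (per-gene deletion followed by re-intersection) gives the
  same result whenever the partner's value is also retained.
- **Zero-length branches.** A zero-length *gene* branch is a legitimate 0
  after normalization; a zero-length *reference* branch makes the ratio
  undefined, so that bipartition is dropped (with a warning).
- **Per-pair processing.** The Z-transform is computed per gene on the
  branches retained *for that pair* (after shared-taxon pruning and
  paired outlier deletion), so each pair's statistic is self-contained.
- **Degenerate pairs.** Too few shared taxa, too few aligned branches, or
  (numerically) zero variance produce a *skipped-pair record* carrying a
  reason code, never an exception that aborts a scan, and skipped pairs
  stay inside the Bonferroni family size. Near-constant vectors are
  detected with a relative tolerance (`sd ≤ 10⁻¹² · mean|v|`) because a
  constant ratio computed as `(s·b)/b` is not bit-identical across
  branches.
- **Determinism.** Every stochastic function takes a seed and restores
  the caller's RNG state; bipartition keys and all output orderings use
  C-collation (radix) sorting, so identical configurations give
  byte-identical outputs regardless of locale.
- **Scale invariance has a boundary.** Multiplying all of one gene's
  branch lengths by a constant leaves `r` and `p` unchanged *as long as
  no normalized branch crosses the outlier threshold*; the filter acts on
  the scale-carrying normalized values by design.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
explicit-sum Pearson/t computation, a four-point-condition quartet
labeler on patristic distances, exhaustive enumeration of equal-size edge
sets for the Jaccard null, full rank-permutation enumeration for the
module contrast, direct combinatorics for the hypergeometric tail, and
`igraph`'s assortativity as a cross-check of the mixing-matrix formula.

Calibration and power are checked at a deliberate desk scale chosen to
give tight Monte-Carlo error at interactive runtimes: null calibration
with 200 replicate scans of 40 independent genes on a 60-taxon tree
(the false-positive rate is measured on each scan's 20 disjoint gene
pairs, because pairs sharing a gene are not independent and a binomial
confidence interval only applies to independent tests), and power with
50 replicates per ρ ∈ {0, 0.3, 0.6, 0.9} of a planted 6-gene group among
20 genes (σ = 0.5, 10% dropout). Under these conditions power at ρ = 0.9
is essentially 1, and is monotone in ρ with the steep rise between 0.3
and 0.6 expected from the t-transform at ~100 branches.

## Known limitations

- Branch correspondence by bipartition *requires* topology-constrained
  gene trees; a free gene-tree topology raises an incongruence error
  rather than silently matching wrong branches.
- Bonferroni control is conservative for the large within-genome scan
  families; the package reports raw p-values alongside, so other
  procedures can be applied downstream.
- The quartet enumeration is exhaustive, not sampled; beyond ~80 taxa a
  subsampled score would be needed.
- The pipeline consumes annotation, interaction and co-fitness tables as
  given; no attempt is made to resolve identifier mismatches beyond exact
  string equality on gene IDs.
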