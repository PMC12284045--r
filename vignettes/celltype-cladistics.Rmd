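---
title: "Cell-type cladistics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type cladistics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellclades)
```

## The question and the model

Homology of cell types — for instance between the retinal pigment
epithelium, melanocytes, pinealocytes, and the pigmented photoreceptors of
tunicate larvae — cannot be read off global transcriptome similarity,
which is sensitive to tissue environment, technical noise, and the choice
of distance and linkage. `cellclades` instead treats cell-type identity as
a heritable regulatory character set: each cell type is a taxon, each
transcription factor (TF) a binary character scored present (1) or absent
(0) in the type's expressed repertoire, and relationships between types
are estimated under the maximum-parsimony (cladistic) criterion — the
preferred tree is the unrooted binary topology requiring the fewest
gains/losses of TF expression to explain the matrix.

The parsimony length of one character on a fixed tree is computed with the
Fitch set algorithm: a post-order pass from an arbitrary rooting keeps,
per node, the set of states attainable without extra cost; when the child
sets intersect the node takes the intersection, otherwise the union at a
cost of one change. The tree length is the sum over characters, and it is
independent of the rooting. Missing states (`NA`, written `?` on disk)
enter as the full state set {0,1}: a taxon with missing data can be
assigned whichever state is cheapest, the standard treatment.

Three search strategies share this scorer (C++ core):

* **exhaustive** — stepwise leaf insertion enumerates each unrooted binary
  topology exactly once ((2n−5)!! topologies) and scores it; used up to 9
  taxa by default.
* **branch-and-bound** — the same enumeration, pruning any partial tree
  whose score already exceeds the best complete tree; because adding taxa
  can only increase the Fitch length, this is exact. The bound is seeded
  with a greedy-addition + NNI-descent tree. Default for 10–14 taxa.
* **nni** — hill-climbing over nearest-neighbour interchanges with 20
  random-restart addition orders (seeded, deterministic); heuristic, for
  larger taxon sets.

All co-optimal topologies found are returned; ties are summarised by the
strict consensus (only bipartitions common to every optimum) rather than
by an arbitrary single-tree pick. An optional outgroup roots trees for
display only — inference is unrooted. Robustness is assessed by a
character-resampling bootstrap: characters are drawn with replacement,
the search re-run, and each reference bipartition annotated with the
fraction of replicates whose strict consensus contains it.

## From counts to characters

Counts are QC-filtered per cell (UMI range 500–20,000, detected genes
800–6,000, complexity `log10(n_genes)/log10(n_umi) > 0.8`, mitochondrial
percentage < 10 by default; all configurable). The complexity score is
implemented as the ratio of logs: the literal reading `log10(genes/UMI)`
is negative for every real cell, so it cannot be the intended filter —
the ratio form is the standard library-complexity score that the 0.8
cutoff presupposes. Genes detected in fewer than 3 cells are optionally
dropped (default 3, configurable), and normalisation scales each cell to
10,000 counts followed by `log1p`.

"Expressed/detected" always means raw count > 0; detection fractions
therefore depend only on the zero pattern and are invariant to depth
scaling. A TF is scored present in a type when detected in **at least
10 %** of the type's cells — the boundary is inclusive by the wording of
the rule, and `frac_expr == 0.10` maps to state 1 (tested). Characters
present in all or in no types carry no grouping signal and are removed
(`filter_informative`), with counts reported per reason.

Cross-species comparison re-keys a character matrix into an orthologous
namespace. When several source paralogs map to one target gene, presence
combines by OR (default: the target's function is available if any
paralog is expressed) or AND. Joining matrices across species unions taxa
and characters; states missing from one species fill with 0 by default —
mirroring the append-a-column construction of a joint matrix — with
`fill = "missing"` available because absence of an ortholog is *not*
evidence of absence of expression (this caveat is the reason both
semantics exist; the filter is re-applied after joining).

## Markers, gene sets, dendrograms, phylostrata

Differential expression uses a two-sided Wilcoxon rank-sum test (normal
approximation with tie correction and continuity correction — verified
against `stats::wilcox.test` in the tests), restricted to genes detected
in ≥ 25 % of either group, with Benjamini–Hochberg adjustment within each
comparison; a Welch t-test is available as a config switch. One
fold-change convention is fixed everywhere:
`avg_log2FC = log2((mean(expm1 x_A)+1)/(mean(expm1 x_B)+1))` — log2 with a
pseudocount of 1 on de-logged means. The shared program of a focal cluster
pair merges the two clusters and tests the merged group against all other
cells at a stringent threshold (`avg_log2FC > 3`). Gene-set scores are the
per-cell mean over the set minus the mean over a size-matched control set
drawn from 25 average-expression bins with a fixed seed, so random sets
score near zero.

The expression dendrogram uses `1 − Pearson` distances between cluster
mean-expression profiles under Ward linkage (`ward.D2`, the variant
consistent with squared-Euclidean updates on a dissimilarity). Constant
profiles raise an error rather than propagating `NaN` correlations.

The chromatin workflow keeps peaks detected in ≥ 1 % of cells (inclusive),
removes peaks overlapping (≥ 1 bp) strand-aware promoter windows
(2,000 bp upstream to 200 bp downstream of each TSS, flipped on the minus
strand) or gene bodies, TF-IDF-weights the remainder
(`ln(1 + 10^4 · tf · idf)`, cells as documents), and embeds by truncated
SVD. Component 1 is dropped by default (it tracks sequencing depth;
`component_range` 2..30). Per-type centroids are compared under four
metrics — euclidean, maximum (Chebyshev), manhattan, canberra — with
complete linkage by default; the source procedure did not name its
linkage, so it is config-exposed. Canberra terms with 0/0 contribute 0
(base R's `dist` omits-and-rescales such terms instead, so Canberra is
computed directly). BED inputs are 0-based half-open and overlap means
≥ 1 shared base.

Phylostrata are integer gene-age classes 1 (cellular LCA) to 20
(species-specific); the map is an input table, never re-derived. "Young"
genes are those at stratum ≥ 10 — the vertebrate boundary, inclusive per
the "10 and above" rule. Young-gene enrichment of a set against a
background is a one-sided hypergeometric upper-tail test on the 2×2
young/old × in/out table, cross-checked against a direct `choose()` tail
sum and a 10,000-draw permutation in the tests. Gene matching is
case-sensitive on symbols; identifier conversion is an input table, not
code.

## The synthetic-data generator

The generator is the package's ground-truth instrument, not a toy: a Yule
(pure-birth) tree over `n_types` cell types; binary TF characters evolving
independently along it (root state Bernoulli(`root_presence_freq`); per
branch, gain with probability `p_gain`, loss with `p_loss`; branch lengths
deliberately ignored — only presence/absence transitions matter under the
cladistic model); negative-binomial counts parameterised by (mean, size)
with variance `mean + mean²/size` — TF genes at `mu_on = 5` where present
and `mu_off = 0.05` where absent, so a present TF is detected in ≈ 98 % of
cells (NB zero probability `(1+mu/size)^(−size)` ≈ 0.017 at size 10) and
an absent one in ≈ 5 %, placing the two states far on either side of the
10 % binarization boundary. Background genes get lognormal base means and
per-type log2 fold-change effects ~ Normal(0,1), except for
`n_strong_markers` planted markers per type at log2FC = 4. Planted
markers use a fixed baseline of 2 counts rather than a lognormal draw:
canonical markers are robustly expressed genes, and a "strong marker"
planted on a baseline of 0.02 counts would be undetectable by
construction, making the planted truth meaningless. Defaults (12 types,
50 TFs, 500 background genes, 200 cells/type, flip probability 0.05) are
the package's reference validation regime.

The generator does **not** emulate doublets, ambient RNA, or batch
effects — integration is upstream of this package and cluster labels are
inputs. Passing tests on synthetic data therefore demonstrate correctness
of the algorithms under the stated generative model, not robustness to
real-data artefacts.

### What the planted-recovery experiment shows

With flip probability 0.05 per branch on a 12-taxon tree (22 rooted
branches), each character incurs ≈ 1.1 expected changes and roughly 30 %
of characters change twice or more. That much homoplasy means the planted
topology frequently scores one or two steps above the global optimum:
binarization reproduces the planted character states essentially
perfectly (0–1 mismatched cells per dataset), and the search provably
finds the true optimum (it matches brute-force enumeration and
independent implementations character-for-character), yet exact topology
recovery at this noise level is rare (~5–10 % of seeds; the planted tree
ties the optimum in ~25 %). This is a property of the evolutionary
regime, not of the implementation: halving the flip probability or
doubling the characters makes recovery routine. The acceptance script
reports the honestly measured recovery fraction at the reference regime
alongside `planted_attains_optimum_pct`.

## Numerical and design choices

* Exact searches are deterministic; the NNI heuristic and the bootstrap
  take explicit seeds, and all seeds are recorded in run manifests.
* Branch-and-bound taxon order is the fixed input order with a
  greedy+NNI upper bound; pruning uses strictly-greater comparison so all
  co-optimal trees are retained.
* Wilcoxon variance uses the tie-corrected normal approximation; groups
  of fewer than 3 cells are an error (the rank test has no useful power
  there).
* `search_mp_tree` errors on < 3 taxa or on a matrix with no informative
  character; `normalize_counts` errors on zero-count cells by name;
  malformed BED lines error with their line number; QC removing every
  cell errors with the per-criterion breakdown.
* Validation problem sizes: the oracle comparisons run 100 random
  matrices at 5–7 taxa (where all topologies and all ancestral labelings
  can be enumerated independently) and 100 at 8 taxa for
  branch-and-bound-vs-exhaustive; recovery and marker experiments run 20
  seeds each at the reference regime. These sizes give the comparisons
  power while keeping the whole suite around a minute on one CPU.

## Limitations

* Parsimony is exact only up to ~14 taxa here; beyond that the NNI
  heuristic gives no optimality guarantee (restarts mitigate).
* The Fitch scorer assumes binary characters on binary trees; consensus
  trees are for display, not re-scoring.
* Wilcoxon p-values use the asymptotic approximation, adequate for the
  group sizes this workflow targets (tens of cells and up).
* Orthology, phylostratum maps, and cluster labels are inputs; errors in
  them propagate undetected.
* The three run-level pipelines exchange data through files; they are
  deterministic given config + seed, and the manifest hash makes reruns
  verifiable.
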