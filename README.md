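# cellclades

Cladistic inference of cell-type homology from single-cell data.

Deciding whether two cell types — say retinal pigment epithelium and
melanocytes — are homologous (descendants of one ancestral cell type) or
merely convergent requires comparing their gene-regulatory identities, not
just their global transcriptomes. `cellclades` implements the
transcription-factor cladistics workflow for that question: each cell type
(cluster) becomes a **taxon**, each transcription factor becomes a binary
**character** (1 = expressed in the type, 0 = not), and the relationships
between types are estimated as the **maximum-parsimony tree** over the
resulting character matrix, i.e. the unrooted topology *T* minimising the
total Fitch length

L(T) = Σ_c min over ancestral labelings of (number of 0↔1 changes of character c on T),

the tree requiring the fewest evolutionary gains and losses of TF
expression to explain the observed repertoires. Around that core the
package provides every stage of the workflow:

- **Simulation with a planted phylogeny** (`sim_config()`,
  `simulate_celltype_data()`): a Yule cell-type tree, binary TF characters
  gained/lost along its branches, negative-binomial counts whose per-type
  means depend on the character state, background genes with planted
  markers, a 20-level phylostratum map, and a partially many-to-one
  ortholog table — so the whole pipeline is testable end-to-end against
  known truth.
- **Preprocessing** (`qc_filter()`, `normalize_counts()`,
  `cluster_profiles()`): UMI/gene/complexity/mitochondrial QC, library-size
  normalisation `x = ln(1 + 10^4 · c/total)`, per-cluster mean expression
  and detection fractions.
- **Markers** (`find_markers()`, `shared_program()`,
  `category_fraction()`, `score_gene_set()`): Wilcoxon rank-sum
  differential expression with detection-fraction and fold-change
  thresholds, shared gene programs of a focal cluster pair, gene-category
  fractions, and bin-matched gene-set scores.
- **Characters** (`binarize_characters()`, `filter_informative()`,
  `map_orthologs()`, `join_character_matrices()`): presence/absence calls
  at the ≥10 % detection rule, removal of uninformative constant
  characters, and cross-species harmonisation through ortholog maps.
- **Parsimony** (`fitch_score()`, `search_mp_tree()`,
  `strict_consensus()`, `bootstrap_support()`, `robinson_foulds()`): an
  exact Fitch-based search (exhaustive ≤ 9 taxa, branch-and-bound ≤ 14,
  NNI heuristic beyond; Rcpp core), all co-optimal topologies, strict
  consensus, character-resampling bootstrap, Newick/NEXUS I/O.
- **Dendrograms** (`expression_dendrogram()`, `filter_peaks()`,
  `exclude_promoter_and_genic()`, `tfidf_lsi()`,
  `centroid_distance_tree()`): correlation/Ward trees on expression
  centroids and chromatin-accessibility trees via TF-IDF → LSI → per-type
  centroids under euclidean/maximum/manhattan/canberra metrics, with
  strand-aware promoter (−2000/+200 around the TSS) and gene-body
  exclusion.
- **Phylostratigraphy** (`assign_strata()`, `select_young()`,
  `young_gene_enrichment()`): gene-age distributions over 20 phylostrata,
  selection of vertebrate-and-younger genes (stratum ≥ 10), and
  hypergeometric young-gene enrichment.
- **Pipelines** (`run_homology_analysis()`, `run_phylostrat_analysis()`,
  `run_chromatin_analysis()`): orchestrated runs from files (MatrixMarket +
  TSV/BED/GMT) to TSV/Newick/JSON report bundles with a config-hash
  manifest.

## Worked example

Simulate eight cell types with a known phylogeny, run the pipeline, and
infer the tree:

```r
library(cellclades)

cfg <- sim_config(n_types = 8, n_tf = 40, n_background = 200,
                  cells_per_type = 100, p_gain = 0.05, p_loss = 0.05,
                  seed = 42)
sim  <- simulate_celltype_data(cfg)
x    <- normalize_counts(sim$counts)
prof <- cluster_profiles(x, sim$counts)
cm   <- filter_informative(binarize_characters(prof, sim$tf_list))
#> filter_informative: dropped 16 all-present, 8 all-absent, 0 all-missing; 16 kept

res <- search_mp_tree(cm)
summary(res)
#> Maximum-parsimony search (exhaustive)
#>   taxa: 8; best score: 17 changes; co-optimal topologies: 1
#>   topologies examined: 10,395
#> Unique optimal topology:
#>   ((((T8,((T7,T3),T6)),T5),T4),T2,T1);

robinson_foulds(res$trees[[1]], sim$truth$true_tree)
#> [1] 0
```

The binarized matrix keeps 16 informative TF characters; scoring all
10,395 unrooted 8-taxon topologies finds a unique optimum of 17 gain/loss
events, and the inferred topology is identical to the planted tree
(Robinson–Foulds distance 0). Marker detection on the same simulation
recovers the planted cell-type markers at a stringent threshold:

```r
head(find_markers(x, sim$counts, group_A = "T3", logfc_min = 3), 3)
#>   gene cluster_A cluster_B avg_log2FC  p_value    p_adj pct_A pct_B
#> 1 BG14        T3      rest       4.01 3.83e-59 1.95e-57     1 0.833
#> 2 BG15        T3      rest       3.95 4.18e-59 1.95e-57     1 0.846
#> 3 BG11        T3      rest       3.86 4.29e-59 1.95e-57     1 0.850
```

`avg_log2FC` is `log2((mean(expm1 x_A)+1)/(mean(expm1 x_B)+1))`; p-values
are two-sided Wilcoxon rank-sum with Benjamini–Hochberg adjustment.

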