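#' Configuration for the planted-phylogeny simulator
#'
#' Bundles every knob of the synthetic single-cell generator: K cell types
#' related by a known (Yule) tree, binary TF characters gained/lost along
#' its branches, negative-binomial counts whose per-type means depend on the
#' character state, and background genes with per-type log2 fold-change
#' effects, a configurable number of which are planted strong markers.
#'
#' The negative binomial is parameterized by (mean, size) with variance
#' `mean + mean^2/size`.
#'
#' @param n_types number of cell types (taxa), >= 2.
#' @param n_tf number of transcription-factor characters.
#' @param n_background number of non-TF background genes.
#' @param cells_per_type cells simulated per type, >= 1.
#' @param p_gain,p_loss per-branch probabilities of a 0->1 gain / 1->0 loss.
#' @param root_presence_freq probability a character is present at the root.
#' @param mu_on,mu_off negative-binomial mean counts for a TF in a type
#'   where it is present / absent (`mu_on > mu_off >= 0`).
#' @param nb_dispersion negative-binomial size parameter (> 0).
#' @param n_strong_markers planted strong background markers per type.
#' @param strong_lfc true log2 fold change of the planted markers.
#' @param marker_base_mean baseline negative-binomial mean (counts) of the
#'   planted markers; canonical cell-type markers are robustly expressed,
#'   so the default is a clearly detectable 2 counts rather than a draw
#'   from the background lognormal.
#' @param background_sdlog sd of the lognormal base-mean distribution for
#'   background genes (meanlog 0).
#' @param effect_sd sd of the Normal(0, effect_sd) per-type log2FC effects
#'   on non-planted background genes.
#' @param seed integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_types = 12L, n_tf = 50L, n_background = 500L,
                       cells_per_type = 200L, p_gain = 0.05, p_loss = 0.05,
                       root_presence_freq = 0.5, mu_on = 5, mu_off = 0.05,
                       nb_dispersion = 10, n_strong_markers = 5L,
                       strong_lfc = 4, marker_base_mean = 2,
                       background_sdlog = 1, effect_sd = 1, seed = 1L) {
  cfg <- list(n_types = as.integer(n_types), n_tf = as.integer(n_tf),
              n_background = as.integer(n_background),
              cells_per_type = as.integer(cells_per_type),
              p_gain = p_gain, p_loss = p_loss,
              root_presence_freq = root_presence_freq,
              mu_on = mu_on, mu_off = mu_off, nb_dispersion = nb_dispersion,
              n_strong_markers = as.integer(n_strong_markers),
              strong_lfc = strong_lfc, marker_base_mean = marker_base_mean,
              background_sdlog = background_sdlog,
              effect_sd = effect_sd, seed = as.integer(seed))
  probs <- c(cfg$p_gain, cfg$p_loss, cfg$root_presence_freq)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_types < 2L) stop("n_types must be >= 2")
  if (cfg$cells_per_type < 1L) stop("cells_per_type must be >= 1")
  if (!(cfg$mu_on > cfg$mu_off && cfg$mu_off >= 0)) {
    stop("need mu_on > mu_off >= 0")
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Sample a random cell-type tree under a Yule (pure-birth) process
#'
#' @param n_types number of leaves (>= 2); tips are labeled `T1..Tn`.
#' @param seed integer RNG seed; the tree is deterministic given it.
#' @return A rooted binary `phylo` tree with positive branch lengths.
#' @export
sample_yule_tree <- function(n_types, seed = 1L) {
  if (n_types < 2L) stop("n_types must be >= 2")
  set.seed(seed)
  tr <- ape::rphylo(n_types, birth = 1, death = 0)
  tr$tip.label <- paste0("T", seq_len(n_types))
  tr
}

#' Evolve binary TF characters along a tree
#'
#' Each character evolves independently: the root state is
#' Bernoulli(`root_presence_freq`); along every branch an absent character
#' is gained with probability `p_gain` and a present one lost with
#' probability `p_loss`. Branch lengths are ignored (constant per-branch
#' flip probabilities): only presence/absence changes matter, matching the
#' cladistic treatment of TF repertoires.
#'
#' @param tree rooted `phylo` tree (>= 2 leaves).
#' @param n_tf number of characters; named `TF1..TFn`.
#' @param p_gain,p_loss,root_presence_freq see [sim_config()].
#' @param seed integer RNG seed.
#' @return A [character_matrix()] over the tree's tips, with the per-branch
#'   flip count in attribute `n_flips` and branch count in `n_branch_draws`.
#' @export
evolve_characters <- function(tree, n_tf, p_gain = 0.05, p_loss = 0.05,
                              root_presence_freq = 0.5, seed = 1L) {
  if (length(tree$tip.label) < 2L) stop("tree must have >= 2 leaves")
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  n <- length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  edge <- tree$edge
  states <- matrix(NA_integer_, n_nodes, n_tf)
  states[n + 1L, ] <- rbinom(n_tf, 1L, root_presence_freq)
  n_flips <- 0L
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    s <- states[p, ]
    flip_up <- rbinom(n_tf, 1L, p_gain) == 1L & s == 0L
    flip_dn <- rbinom(n_tf, 1L, p_loss) == 1L & s == 1L
    s[flip_up] <- 1L
    s[flip_dn] <- 0L
    n_flips <- n_flips + sum(flip_up | flip_dn)
    states[ch, ] <- s
  }
  m <- states[seq_len(n), , drop = FALSE]
  dimnames(m) <- list(tree$tip.label, paste0("TF", seq_len(n_tf)))
  out <- character_matrix(m)
  attr(out, "n_flips") <- n_flips
  attr(out, "n_branch_draws") <- nrow(edge) * n_tf
  out
}

#' Simulate a count matrix from planted TF characters
#'
#' TF genes draw negative-binomial counts with mean `mu_on` in types where
#' the character is present and `mu_off` where absent. Background genes get
#' a lognormal base mean shared across types, multiplied per type by
#' `2^log2FC` where the log2FC effects are Normal(0, `effect_sd`) except for
#' `n_strong_markers` planted markers per type with log2FC = `strong_lfc`.
#'
#' @param true_characters a [character_matrix()]; its taxa define the types.
#' @param config a [sim_config()]; its `seed` drives all randomness.
#' @return A list with `counts` (a [cell_counts()] object, cells x genes)
#'   and `truth` (list: `true_characters`, `true_labels`,
#'   `true_marker_effects` genes x types log2FC matrix, `base_means`).
#' @export
simulate_counts <- function(true_characters, config) {
  stopifnot(inherits(config, "sim_config"))
  cm <- as_cm(true_characters)
  types <- rownames(cm)
  K <- length(types)
  set.seed(config$seed + 1L)
  n_tf <- ncol(cm)
  n_bg <- config$n_background
  genes <- c(colnames(cm), if (n_bg > 0L) paste0("BG", seq_len(n_bg)))

  base_means <- if (n_bg > 0L) {
    rlnorm(n_bg, meanlog = 0, sdlog = config$background_sdlog)
  } else numeric(0)
  effects <- matrix(0, n_bg, K, dimnames = list(genes[-seq_len(n_tf)], types))
  if (n_bg > 0L) {
    effects[] <- rnorm(n_bg * K, 0, config$effect_sd)
    # planted strong markers: disjoint gene blocks, one block per type
    n_strong <- min(config$n_strong_markers, n_bg %/% max(1L, K))
    if (n_strong > 0L) {
      for (t in seq_len(K)) {
        idx <- ((t - 1L) * n_strong + 1L):(t * n_strong)
        effects[idx, ] <- 0
        effects[idx, t] <- config$strong_lfc
        base_means[idx] <- config$marker_base_mean
      }
    }
  }

  n_cells <- K * config$cells_per_type
  labels <- rep(types, each = config$cells_per_type)
  counts <- matrix(0L, n_cells, length(genes))
  for (t in seq_len(K)) {
    rows <- which(labels == types[t])
    mu_tf <- ifelse(unclass(cm)[t, ] == 1L, config$mu_on, config$mu_off)
    mu_bg <- base_means * 2^effects[, t]
    mu <- c(mu_tf, mu_bg)
    counts[rows, ] <- matrix(
      rnbinom(length(rows) * length(mu), mu = rep(mu, each = length(rows)),
              size = config$nb_dispersion),
      nrow = length(rows))
  }
  dimnames(counts) <- list(sprintf("cell%05d", seq_len(n_cells)), genes)
  cc <- cell_counts(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
                    cluster = labels)
  truth <- list(true_characters = cm, true_labels = labels,
                true_marker_effects = effects, base_means = base_means)
  list(counts = cc, truth = truth)
}

#' Simulate a full dataset with a planted cell-type phylogeny
#'
#' Convenience wrapper: samples a Yule tree, evolves TF characters along it,
#' simulates counts, and builds a phylostratum map and an ortholog table for
#' the simulated genes.
#'
#' @param config a [sim_config()].
#' @return A list: `counts` ([cell_counts()]), `truth` (with `true_tree`,
#'   `true_characters`, `true_labels`, `true_marker_effects`), `tf_list`,
#'   `psmap` ([make_phylostratum_map()]), `orthologs`.
#' @export
simulate_celltype_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- sample_yule_tree(config$n_types, seed = config$seed)
  chars <- evolve_characters(tree, config$n_tf, config$p_gain, config$p_loss,
                             config$root_presence_freq, seed = config$seed)
  sim <- simulate_counts(chars, config)
  sim$truth$true_tree <- tree
  genes <- colnames(sim$counts$counts)
  sim$tf_list <- colnames(chars)
  sim$psmap <- make_phylostratum_map(genes, seed = config$seed + 2L)
  sim$orthologs <- make_ortholog_map(paste0("cg-", genes), genes,
                                     many_to_one_fraction = 0.1,
                                     seed = config$seed + 3L)
  sim$config <- config
  sim
}

#' Assign genes to phylostrata
#'
#' Uniformly assigns each gene an integer evolutionary age class
#' (phylostratum) in `1..n_strata`; a configurable fraction is left
#' unmapped, emulating genes absent from the evolutionary map.
#'
#' @param genes character vector of gene ids.
#' @param n_strata number of strata (default 20, cellular LCA to mouse).
#' @param unmapped_fraction probability a gene is left unmapped.
#' @param seed integer RNG seed.
#' @return A `phylostratum_map`: list with `strata` (named integer vector),
#'   `unmapped` (character vector), `n_strata`, `map_source`.
#' @export
make_phylostratum_map <- function(genes, n_strata = 20L,
                                  unmapped_fraction = 0, seed = 1L) {
  if (length(genes) == 0L) stop("gene list is empty")
  genes <- unique(genes)
  set.seed(seed)
  unmapped <- runif(length(genes)) < unmapped_fraction
  strata <- sample.int(n_strata, sum(!unmapped), replace = TRUE)
  phylostratum_map(setNames(strata, genes[!unmapped]),
                   unmapped = genes[unmapped], n_strata = n_strata,
                   map_source = "synthetic uniform assignment")
}

#' Simulate an ortholog conversion table
#'
#' Builds (source, target) gene pairs for a second "species": most targets
#' receive one source gene, a configurable fraction receive two (paralog
#' pairs mapping many-to-one), and a fraction of sources stays unmapped.
#'
#' @param source_genes,target_genes character vectors.
#' @param many_to_one_fraction fraction of mapped targets receiving two
#'   source genes.
#' @param unmapped_source_fraction fraction of source genes left unmapped.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `source_gene`, `target_gene`.
#' @export
make_ortholog_map <- function(source_genes, target_genes,
                              many_to_one_fraction = 0.1,
                              unmapped_source_fraction = 0.1, seed = 1L) {
  if (length(source_genes) == 0L || length(target_genes) == 0L) {
    stop("gene lists must be non-empty")
  }
  source_genes <- unique(source_genes)
  target_genes <- unique(target_genes)
  set.seed(seed)
  keep <- runif(length(source_genes)) >= unmapped_source_fraction
  src <- source_genes[keep]
  n_one2one <- min(length(src), length(target_genes))
  tgt <- sample(target_genes, n_one2one)
  src1 <- sample(src, n_one2one)
  pairs <- data.frame(source_gene = src1, target_gene = tgt,
                      stringsAsFactors = FALSE)
  extra_src <- setdiff(src, src1)
  n_many <- min(length(extra_src), round(many_to_one_fraction * n_one2one))
  if (n_many > 0L) {
    pairs <- rbind(pairs, data.frame(
      source_gene = sample(extra_src, n_many),
      target_gene = sample(tgt, n_many),
      stringsAsFactors = FALSE))
  }
  unique(pairs)
}

#' Write a simulated dataset to disk
#'
#' Emits the 10x-style MatrixMarket triple (`matrix.mtx`, `genes.tsv`,
#' `barcodes.tsv`), cluster labels (`labels.tsv`), the planted tree
#' (`true_tree.nwk`), characters (`true_characters.tsv`), the phylostratum
#' map (`phylostrata.tsv`), the ortholog table (`orthologs.tsv`), the TF
#' list (`tf_list.tsv`) and a JSON run manifest recording all seeds.
#'
#' @param sim result of [simulate_celltype_data()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(sim$counts, dir)
  ape::write.tree(sim$truth$true_tree, file.path(dir, "true_tree.nwk"))
  write_character_matrix(sim$truth$true_characters,
                         file.path(dir, "true_characters.tsv"))
  write_phylostratum_map(sim$psmap, file.path(dir, "phylostrata.tsv"))
  utils::write.table(sim$orthologs, file.path(dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$tf_list, file.path(dir, "tf_list.tsv"))
  manifest <- c(unclass(sim$config), list(package = "cellclades"))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
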