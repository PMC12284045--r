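test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_types = 1), "n_types")
  expect_error(sim_config(p_gain = 1.2), "probabilities")
  expect_error(sim_config(mu_on = 0.05, mu_off = 0.05), "mu_on > mu_off")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(cells_per_type = 0), "cells_per_type")
})

test_that("sample_yule_tree gives the right shape and is deterministic", {
  t2 <- sample_yule_tree(2, seed = 11)
  expect_identical(sort(t2$tip.label), c("T1", "T2"))  # single cherry
  expect_identical(ape::write.tree(sample_yule_tree(4, seed = 1)),
                   ape::write.tree(sample_yule_tree(4, seed = 1)))
  t8 <- ape::unroot(sample_yule_tree(8, seed = 7))
  expect_identical(length(t8$tip.label), 8L)
  expect_identical(t8$Nnode, 6L)        # unrooted binary: n - 2 internals
  expect_identical(nrow(t8$edge), 13L)  # and 2n - 3 edges
  expect_true(all(t8$edge.length > 0))
  expect_error(sample_yule_tree(1), "n_types")
})

test_that("character evolution respects degenerate flip probabilities", {
  tr <- sample_yule_tree(6, seed = 2)
  frozen <- evolve_characters(tr, 30, p_gain = 0, p_loss = 0,
                              root_presence_freq = 0.5, seed = 3)
  expect_true(all(apply(unclass(frozen), 2, function(col) length(unique(col)) == 1L)))
  ones <- evolve_characters(tr, 25, p_gain = 0, p_loss = 0,
                            root_presence_freq = 1, seed = 3)
  expect_true(all(unclass(ones) == 1L))
  # frozen characters are all constant => zero informative characters
  expect_error(suppressMessages(filter_informative(frozen)), "informative")
})

test_that("empirical per-branch flip fraction matches the flip probability", {
  tr <- sample_yule_tree(12, seed = 5)
  cm <- evolve_characters(tr, 50, p_gain = 0.05, p_loss = 0.05,
                          root_presence_freq = 0.5, seed = 5)
  flips <- attr(cm, "n_flips")
  draws <- attr(cm, "n_branch_draws")
  p_hat <- flips / draws
  se <- sqrt(0.05 * 0.95 / draws)
  expect_lt(abs(p_hat - 0.05), 3 * se)
})

test_that("simulated counts reflect the planted characters", {
  tr <- sample_yule_tree(4, seed = 9)
  cm <- evolve_characters(tr, 10, 0.2, 0.2, 0.5, seed = 9)
  cfg0 <- sim_config(n_types = 4, n_tf = 10, n_background = 0,
                     cells_per_type = 50, mu_on = 5, mu_off = 0, seed = 9)
  sim <- simulate_counts(cm, cfg0)
  prof <- cluster_profiles(normalize_counts(sim$counts), sim$counts)
  # mu_off = 0: absent-state TFs have detection fraction exactly 0
  off <- unclass(cm)[rownames(prof$frac_expr), ] == 0L
  expect_true(all(prof$frac_expr[, colnames(cm)][off] == 0))

  cfg1 <- sim_config(n_types = 4, n_tf = 10, n_background = 0,
                     cells_per_type = 200, mu_on = 5, mu_off = 0.05,
                     nb_dispersion = 10, seed = 9)
  sim1 <- simulate_counts(cm, cfg1)
  prof1 <- cluster_profiles(normalize_counts(sim1$counts), sim1$counts)
  on <- unclass(cm)[rownames(prof1$frac_expr), ] == 1L
  # NB zero probability (1 + mu/size)^(-size) ~ 0.017 << 0.9, so every
  # present-state TF clears the 10% binarization threshold
  expect_true(all(prof1$frac_expr[, colnames(cm)][on] > 0.10))

  sim2 <- simulate_counts(cm, cfg1)
  expect_identical(as.matrix(sim1$counts$counts), as.matrix(sim2$counts$counts))
})

test_that("planted strong markers carry the configured effect", {
  cfg <- sim_config(n_types = 3, n_tf = 5, n_background = 60,
                    cells_per_type = 30, n_strong_markers = 4,
                    strong_lfc = 4, seed = 21)
  sim <- simulate_celltype_data(cfg)
  eff <- sim$truth$true_marker_effects
  for (t in 1:3) {
    idx <- ((t - 1) * 4 + 1):(t * 4)
    expect_true(all(eff[idx, t] == 4))
    expect_true(all(eff[idx, -t] == 0))
  }
  # non-planted effects are standard normal draws: none astronomically large
  expect_true(all(abs(eff[-(1:12), ]) < 6))
})

test_that("phylostratum map generation obeys its contract", {
  genes <- paste0("g", 1:1000)
  ps <- make_phylostratum_map(genes, n_strata = 20, seed = 4)
  expect_true(all(ps$strata >= 1 & ps$strata <= 20))
  expect_length(ps$unmapped, 0L)
  ps2 <- make_phylostratum_map(genes, unmapped_fraction = 0.1, seed = 4)
  n_un <- length(ps2$unmapped)
  se <- sqrt(1000 * 0.1 * 0.9)
  expect_lt(abs(n_un - 100), 3 * se)
  expect_error(make_phylostratum_map(character(0)), "empty")
})

test_that("ortholog map construction and round-trip", {
  src <- paste0("cg", 1:100)
  tgt <- paste0("Mg", 1:80)
  inj <- make_ortholog_map(src, tgt, many_to_one_fraction = 0,
                           unmapped_source_fraction = 0, seed = 6)
  expect_false(anyDuplicated(inj$source_gene) > 0)
  m2o <- make_ortholog_map(src, tgt, many_to_one_fraction = 0.2,
                           unmapped_source_fraction = 0, seed = 6)
  expect_true(any(table(m2o$target_gene) >= 2))
  tmp <- tempfile(fileext = ".tsv")
  write.table(m2o, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_ortholog_map(tmp)
  expect_identical(back$source_gene, m2o$source_gene)
  expect_identical(back$target_gene, m2o$target_gene)
})

test_that("a full simulation writes and reads back identically", {
  cfg <- sim_config(n_types = 4, n_tf = 8, n_background = 40,
                    cells_per_type = 20, seed = 31)
  sim <- simulate_celltype_data(cfg)
  dir <- tempfile()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("matrix.mtx", "genes.tsv", "barcodes.tsv", "labels.tsv",
      "true_tree.nwk", "true_characters.tsv", "phylostrata.tsv",
      "orthologs.tsv", "tf_list.tsv", "run_manifest.json")))))
  back <- read_count_matrix(dir)
  expect_identical(as.matrix(back$counts), as.matrix(sim$counts$counts))
  expect_identical(back$cell_meta$cluster, sim$counts$cell_meta$cluster)
  tr <- ape::read.tree(file.path(dir, "true_tree.nwk"))
  expect_identical(robinson_foulds(tr, sim$truth$true_tree), 0L)
  cm_back <- read_character_matrix(file.path(dir, "true_characters.tsv"))
  expect_identical(unclass(cm_back), unclass(sim$truth$true_characters),
                   ignore_attr = TRUE)
  # identical seeds => byte-identical outputs
  dir2 <- tempfile()
  write_simulation(simulate_celltype_data(cfg), dir2)
  expect_identical(readLines(file.path(dir, "matrix.mtx")),
                   readLines(file.path(dir2, "matrix.mtx")))
})
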