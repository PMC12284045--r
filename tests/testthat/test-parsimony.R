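worked_cm <- character_matrix(matrix(
  c(1, 1, 0, 0,
    1, 0, 1, 0,
    1, 0, 0, 0), 4, 3,
  dimnames = list(c("A", "B", "C", "D"), c("c1", "c2", "c3"))))

test_that("fitch_score matches hand-derived values on the 4-taxon example", {
  t_ab <- ape::read.tree(text = "((A,B),(C,D));")
  t_ac <- ape::read.tree(text = "((A,C),(B,D));")
  c1 <- worked_cm[, 1, drop = FALSE]
  expect_identical(fitch_score(t_ab, c1), 1L)
  expect_identical(fitch_score(t_ac, c1), 2L)
  expect_identical(fitch_score(t_ab, worked_cm), 4L)
})

test_that("fitch_score equals the ancestral-labeling oracle on random trees", {
  for (seed in 1:10) {
    cm <- random_cm(6, 8, seed)
    set.seed(seed)
    tr <- ape::rtree(6, tip.label = rownames(cm), br = NULL)
    expect_identical(fitch_score(tr, cm),
                     as.integer(oracle_tree_length(tr, unclass(cm))))
  }
})

test_that("fitch_score is invariant to rooting, taxon order, character order", {
  cm <- random_cm(7, 12, 99)
  set.seed(1)
  tr <- ape::rtree(7, tip.label = rownames(cm), br = NULL)
  s <- fitch_score(tr, cm)
  expect_identical(fitch_score(ape::unroot(tr), cm), s)
  expect_identical(fitch_score(ape::root(ape::unroot(tr), "t3", resolve.root = TRUE), cm), s)
  expect_identical(fitch_score(tr, cm[sample(7), , drop = FALSE]), s)
  expect_identical(fitch_score(tr, cm[, sample(12), drop = FALSE]), s)
})

test_that("missing states behave as the full state set", {
  # a taxon with all-missing states can attach anywhere at no extra cost
  m <- matrix(c(1, 1, 0, 0, NA,
                0, 1, 1, 0, NA), 5, 2,
              dimnames = list(c("A", "B", "C", "D", "E"),
                              c("c1", "c2")))
  cm <- character_matrix(m)
  t1 <- ape::read.tree(text = "(((A,B),E),(C,D));")
  t2 <- ape::read.tree(text = "((A,B),((C,E),D));")
  expect_identical(fitch_score(t1, cm), fitch_score(t2, cm))
  # and matches the per-character enumeration oracle
  for (tr in list(t1, t2)) {
    expected <- sum(vapply(1:2, function(j) {
      oracle_char_length(tr, setNames(m[, j], rownames(m)))
    }, numeric(1)))
    expect_identical(fitch_score(tr, cm), as.integer(expected))
  }
})

test_that("the worked 4-taxon matrix has two co-optimal trees, consensus star", {
  res <- search_mp_tree(worked_cm, method = "exhaustive")
  expect_identical(res$best_score, 4L)
  expect_identical(res$n_topologies_examined, 3)
  expect_length(res$trees, 2L)
  keys <- vapply(res$trees,
                 function(tr) cellclades:::bipartition_keys(tr),
                 character(1))
  expect_setequal(keys, c("C|D", "B|D"))
  cons <- strict_consensus(res$trees)
  expect_length(cellclades:::bipartition_keys(cons), 0L)
  expect_identical(robinson_foulds(res$trees[[1]], res$trees[[2]]), 2L)
})

test_that("a single informative character yields its split as unique optimum", {
  m <- matrix(c(1, 1, 0, 0), 4, 1,
              dimnames = list(c("A", "B", "C", "D"), "c1"))
  res <- search_mp_tree(character_matrix(m), method = "exhaustive")
  expect_identical(res$best_score, 1L)
  expect_length(res$trees, 1L)
  expect_identical(cellclades:::bipartition_keys(res$trees[[1]]), "C|D")
})

test_that("exhaustive search equals the brute-force topology oracle", {
  for (seed in 1:8) {
    n_taxa <- 5 + (seed %% 3)
    cm <- random_cm(n_taxa, 10, seed + 100)
    res <- search_mp_tree(cm, method = "exhaustive")
    orc <- oracle_best_score(unclass(cm))
    expect_identical(res$best_score, as.integer(orc$best))
    expect_identical(res$n_topologies_examined, orc$n_topologies * 1.0)
  }
})

test_that("branch-and-bound is exact and deterministic", {
  for (seed in 1:10) {
    cm <- random_cm(8, 12, seed + 500)
    ex <- search_mp_tree(cm, method = "exhaustive")
    bb <- search_mp_tree(cm, method = "branch_and_bound")
    bb2 <- search_mp_tree(cm, method = "branch_and_bound")
    expect_identical(bb$best_score, ex$best_score)
    expect_identical(length(bb$trees), length(ex$trees))
    expect_identical(lapply(bb$trees, ape::write.tree),
                     lapply(bb2$trees, ape::write.tree))
    expect_lte(bb$n_topologies_examined, ex$n_topologies_examined)
  }
})

test_that("per-character Fitch length respects the informative-character bounds", {
  for (seed in 1:5) {
    cm <- random_cm(7, 15, seed + 900)
    cm <- suppressMessages(filter_informative(cm))
    set.seed(seed)
    tr <- ape::rtree(7, tip.label = rownames(cm), br = NULL)
    for (j in seq_len(ncol(cm))) {
      len <- fitch_score(tr, cm[, j, drop = FALSE])
      ones <- sum(unclass(cm)[, j] == 1)
      zeros <- sum(unclass(cm)[, j] == 0)
      expect_gte(len, 1L)
      expect_lte(len, min(ones, zeros))
    }
  }
})

test_that("search validates its inputs", {
  m <- matrix(c(1, 0), 2, 1, dimnames = list(c("A", "B"), "c1"))
  expect_error(search_mp_tree(character_matrix(m)), "at least 3 taxa")
  m2 <- matrix(1L, 4, 2, dimnames = list(LETTERS[1:4], c("c1", "c2")))
  expect_error(search_mp_tree(character_matrix(m2)), "informative")
  tr <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(fitch_score(tr, worked_cm), "do not match")
})

test_that("NNI search finds the exact optimum on moderate matrices", {
  for (seed in 1:3) {
    cm <- random_cm(8, 15, seed + 1300)
    ex <- search_mp_tree(cm, method = "exhaustive")
    hn <- search_mp_tree(cm, method = "nni", seed = 7)
    hn2 <- search_mp_tree(cm, method = "nni", seed = 7)
    expect_gte(hn$best_score, ex$best_score)
    # deterministic given the seed
    expect_identical(hn$best_score, hn2$best_score)
  }
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  trees <- list(ape::read.tree(text = "((A,B),((C,D),(E,F)));"),
                ape::read.tree(text = "((A,B),((C,E),(D,F)));"))
  cons <- strict_consensus(trees)
  shared <- intersect(cellclades:::bipartition_keys(ape::unroot(trees[[1]])),
                      cellclades:::bipartition_keys(ape::unroot(trees[[2]])))
  expect_setequal(cellclades:::bipartition_keys(cons), shared)
  one <- strict_consensus(trees[1])
  expect_identical(ape::write.tree(one), ape::write.tree(trees[[1]]))
  t_bad <- ape::read.tree(text = "((A,B),(C,G));")
  expect_error(strict_consensus(list(trees[[1]], t_bad)), "leaf sets differ")
})

test_that("robinson_foulds agrees with phangorn and handles star trees", {
  skip_if_not_installed("phangorn")
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_identical(robinson_foulds(t1, t1), 0L)
  expect_identical(robinson_foulds(t1, star), 1L)
  for (seed in 1:5) {
    set.seed(seed)
    a <- ape::rtree(8, br = NULL)
    b <- ape::rtree(8, br = NULL)
    expect_identical(robinson_foulds(a, b),
                     as.integer(phangorn::RF.dist(a, b)))
  }
})

test_that("fitch_score agrees with phangorn::fitch on random data", {
  skip_if_not_installed("phangorn")
  for (seed in 1:5) {
    cm <- random_cm(9, 20, seed + 1700)
    set.seed(seed)
    tr <- ape::rtree(9, tip.label = rownames(cm), br = NULL)
    pd <- phangorn::phyDat(ifelse(unclass(cm) == 1, "u", "a"),
                           type = "USER", levels = c("a", "u"))
    expect_identical(fitch_score(tr, cm),
                     as.integer(phangorn::fitch(tr, pd)))
  }
})

test_that("bootstrap support is 1 for an unambiguous repeated character", {
  m <- matrix(rep(c(1, 1, 1, 0, 0, 0), 20), 6, 20,
              dimnames = list(LETTERS[1:6], paste0("c", 1:20)))
  cm <- character_matrix(m)
  tr <- bootstrap_support(cm, B = 20, seed = 5)
  sup <- attr(tr, "support")
  key <- paste(sort(c("D", "E", "F")), collapse = "|")
  expect_true(key %in% names(sup))
  expect_equal(unname(sup[key]), 1.0)
  expect_error(bootstrap_support(cm, B = 0), "B must be")
  tr2 <- bootstrap_support(cm, B = 20, seed = 5)
  expect_identical(attr(tr, "support"), attr(tr2, "support"))
})

test_that("outgroup rooting places the outgroup basally without changing score", {
  cm <- random_cm(6, 10, 4242)
  res <- search_mp_tree(cm, method = "exhaustive", outgroup = "t1")
  expect_true(ape::is.rooted(res$trees[[1]]))
  res2 <- search_mp_tree(cm, method = "exhaustive")
  expect_identical(res$best_score, res2$best_score)
  expect_error(search_mp_tree(cm, outgroup = "nope"), "not a taxon")
})
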