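toy_prof <- function(m) {
  structure(list(mean_expr = m, frac_expr = (m > 0) * 1,
                 n_cells = setNames(rep(5, nrow(m)), rownames(m))),
            class = "cluster_profile")
}

test_that("expression dendrogram distances and merge structure", {
  set.seed(2)
  base <- rnorm(30)
  m <- rbind(A1 = base + rnorm(30, sd = 0.01),
             A2 = base + rnorm(30, sd = 0.01),
             B1 = -base + rnorm(30, sd = 0.01),
             B2 = -base + rnorm(30, sd = 0.01))
  colnames(m) <- paste0("g", 1:30)
  hc <- expression_dendrogram(toy_prof(m))
  # the two tight pairs are sisters
  cl <- cutree(hc, k = 2)
  expect_identical(unname(cl["A1"]), unname(cl["A2"]))
  expect_identical(unname(cl["B1"]), unname(cl["B2"]))
  expect_false(cl[["A1"]] == cl[["B1"]])
  # anticorrelated profiles sit at distance ~2
  d <- 1 - cor(t(m))
  expect_gt(d["A1", "B1"], 1.9)
  # Ward heights are monotone non-decreasing
  expect_true(all(diff(hc$height) >= -1e-12))
  # duplicated profiles merge first at height 0
  m2 <- rbind(m, A1copy = m["A1", ])
  hc2 <- expression_dendrogram(toy_prof(m2))
  expect_lt(hc2$height[1], 1e-6)
  first <- rownames(m2)[-hc2$merge[1, ]]
  expect_setequal(first, c("A1", "A1copy"))
})

test_that("zero-variance profiles raise an error naming the cluster", {
  m <- rbind(K1 = c(1, 2, 3), Kflat = c(2, 2, 2))
  colnames(m) <- paste0("g", 1:3)
  expect_error(expression_dendrogram(toy_prof(m)), "Kflat")
})

random_pm <- function(n_cells = 40, n_peaks = 60, seed = 1, n_types = 3) {
  set.seed(seed)
  m <- matrix(rbinom(n_cells * n_peaks, 4, 0.15), n_cells, n_peaks)
  # guarantee every cell detects something
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  dimnames(m) <- list(paste0("bc", seq_len(n_cells)),
                      paste0("p", seq_len(n_peaks)))
  peaks <- data.frame(chrom = "chr1",
                      start = seq(0, by = 1000, length.out = n_peaks),
                      end = seq(500, by = 1000, length.out = n_peaks))
  peak_matrix(m, peaks, rep(paste0("ty", seq_len(n_types)),
                            length.out = n_cells))
}

test_that("peak filtering keeps the inclusive detection boundary", {
  m <- matrix(0L, 100, 3, dimnames = list(paste0("c", 1:100), NULL))
  m[1, 1] <- 1L          # exactly 1% of cells
  m[1:5, 2] <- 1L        # 5%
  m[, 3] <- 0L           # 0 cells
  m[2, 3] <- 0L
  peaks <- data.frame(chrom = "chr1", start = c(0, 10, 20), end = c(5, 15, 25))
  pm <- peak_matrix(m, peaks, rep("t", 100))
  kept <- filter_peaks(pm, min_cell_frac = 0.01)
  expect_identical(ncol(kept$counts), 2L)     # the 1% peak is kept
  ident <- filter_peaks(pm, min_cell_frac = 0)
  expect_identical(ncol(ident$counts), 3L)    # 0 threshold keeps even 0-cell peaks
  expect_error(filter_peaks(peak_matrix(m * 0L + 0L, peaks, rep("t", 100)),
                            min_cell_frac = 0.5), "removed")
})

test_that("promoter and gene-body exclusion is strand-aware, >= 1 bp overlap", {
  peaks <- data.frame(
    chrom = "chr1",
    start = c(8000, 10150, 30000, 19800, 50000),
    end =   c(8100, 10250, 30100, 19900, 50100))
  m <- matrix(1L, 4, 5, dimnames = list(paste0("c", 1:4), NULL))
  pm <- peak_matrix(m, peaks, rep("t", 4))
  # plus-strand TSS at 10000: window [8000, 10200); minus-strand TSS at
  # 20000 (interval end): window [19800, 22000)
  tss <- data.frame(chrom = "chr1", start = c(10000, 19000),
                    end = c(10001, 20000), name = c("gp", "gm"),
                    strand = c("+", "-"))
  gene <- data.frame(chrom = "chr1", start = 29999, end = 30001)
  out <- exclude_promoter_and_genic(pm, tss, gene)
  # peak 1 inside plus promoter: gone; peak 2 straddles its edge: gone;
  # peak 3 overlaps the gene body by 1 bp: gone; peak 4 inside the
  # minus-strand promoter: gone; peak 5 distal: kept
  expect_equal(out$peaks$start, 50000)
  pm_all <- peak_matrix(m[, 1, drop = FALSE], peaks[1, ], rep("t", 4))
  expect_error(exclude_promoter_and_genic(pm_all, tss, gene), "all peaks")
})

test_that("malformed BED lines error with the line number", {
  tmp <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t200\tnope"), tmp)
  expect_error(read_bed(tmp), "line 2")
  writeLines(c("chr1\t500\t400"), tmp)
  expect_error(read_bed(tmp), "line 1")
  writeLines(c("chr1\t0\t100\tg\t0\t."), tmp)
  expect_error(read_bed(tmp, need_strand = TRUE), "line 1")
})

test_that("TF-IDF matches the stated formula and is depth-invariant", {
  m <- matrix(c(2, 0, 1,
                0, 3, 1,
                4, 4, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("c1", "c2", "c3"), c("p1", "p2", "p3")))
  peaks <- data.frame(chrom = "chr1", start = c(0, 10, 20), end = c(5, 15, 25))
  pm <- peak_matrix(m, peaks, c("a", "b", "c"))
  w <- as.matrix(cellclades:::tfidf_weight(pm$counts, scale = 10000))
  tot <- rowSums(m); idf <- 3 / colSums(m > 0)
  byhand <- log1p(10000 * sweep(sweep(m, 1, tot, "/"), 2, idf, "*"))
  expect_equal(w, byhand, ignore_attr = TRUE)
  # peak detected in every cell has idf 1
  expect_equal(idf[["p1"]], 3 / 2)
  expect_equal(unname(idf[colSums(m > 0) == 3]), numeric(0))
  # doubling one cell's counts leaves its TF-IDF row unchanged
  m2 <- m; m2[2, ] <- m2[2, ] * 2
  pm2 <- peak_matrix(m2, peaks, c("a", "b", "c"))
  w2 <- as.matrix(cellclades:::tfidf_weight(pm2$counts, scale = 10000))
  expect_equal(w2[2, ], w[2, ])
  # zero-peak cell errors by name
  m3 <- m; m3[1, ] <- 0
  expect_error(tfidf_lsi(peak_matrix(m3, peaks, c("a", "b", "c"))), "c1")
})

test_that("centroid trees honor the distance metric definitions", {
  coords <- rbind(c(0, 0), c(1, 3), c(1, 0), c(0, 1))
  labels <- c("A", "B", "C", "D")
  expect_equal(max(abs(coords[1, ] - coords[2, ])), 3)  # chebyshev oracle
  hc_max <- centroid_distance_tree(coords, labels, metric = "maximum")
  expect_s3_class(hc_max, "hclust")
  # canberra on (1,0) vs (0,1): |1|/1 + |1|/1 = 2; 0/0 coords contribute 0
  cb <- cellclades:::canberra_dist(rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(as.numeric(cb), 2)
  # identical centroids merge at height 0
  coords2 <- rbind(coords, c(0, 0))
  hc0 <- centroid_distance_tree(coords2, c(labels, "A2"), metric = "euclidean")
  expect_lt(hc0$height[1], 1e-12)
  expect_error(centroid_distance_tree(coords, labels, metric = "mahalanobis"))
})

test_that("metric inequality d_max <= d_euclid <= d_manhattan on centroids", {
  for (seed in 1:10) {
    set.seed(seed)
    cents <- matrix(rnorm(5 * 8), 5, 8)
    d_max <- as.numeric(dist(cents, method = "maximum"))
    d_euc <- as.numeric(dist(cents, method = "euclidean"))
    d_man <- as.numeric(dist(cents, method = "manhattan"))
    expect_true(all(d_max <= d_euc + 1e-12))
    expect_true(all(d_euc <= d_man + 1e-12))
  }
})

test_that("LSI embedding drops component 1 and is deterministic", {
  pm <- random_pm(seed = 3)
  emb <- tfidf_lsi(pm, n_components = 10)
  expect_identical(emb$component_range, 2:10)
  expect_identical(ncol(emb$coords), 9L)
  expect_true(all(diff(emb$d) <= 1e-9))  # singular values non-increasing
  emb2 <- tfidf_lsi(pm, n_components = 10)
  expect_equal(emb$coords, emb2$coords)
  full <- tfidf_lsi(pm, n_components = 10, drop_first = FALSE)
  expect_identical(full$component_range, 1:10)
})

test_that("chromatin dendrogram merges identical cell types at height 0", {
  pm <- random_pm(n_cells = 30, seed = 5, n_types = 3)
  # duplicate type: make ty3 cells copies of ty1 cells
  m <- as.matrix(pm$counts)
  lab <- pm$cell_types
  m[lab == "ty3", ] <- m[lab == "ty1", ][seq_len(sum(lab == "ty3")), ]
  pm2 <- peak_matrix(m, pm$peaks, lab)
  emb <- tfidf_lsi(pm2, n_components = 8)
  for (metric in c("euclidean", "maximum", "manhattan", "canberra")) {
    hc <- centroid_distance_tree(emb, metric = metric)
    expect_lt(hc$height[1], 1e-8)
    expect_setequal(rownames(cellclades:::centroids(emb$coords, lab))[-hc$merge[1, ]],
                    c("ty1", "ty3"))
  }
})

test_that("dendrograms export to Newick", {
  pm <- random_pm(seed = 11)
  emb <- tfidf_lsi(pm, n_components = 6)
  hc <- centroid_distance_tree(emb, metric = "manhattan")
  nwk <- dendrogram_newick(hc)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, unique(pm$cell_types))
})
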