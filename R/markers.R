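#' Marker-gene detection between cell groups
#'
#' Differential expression of one cluster (or set of clusters) against
#' another or against all remaining cells. Only genes detected in at least
#' `min_pct` of cells on one side are tested. The fold change is
#' `avg_log2FC = log2((mean(expm1(x_A)) + 1) / (mean(expm1(x_B)) + 1))`
#' (pseudocount 1 on de-logged means); p-values come from a two-sided
#' Wilcoxon rank-sum test (normal approximation with tie correction) or a
#' Welch t-test, with Benjamini-Hochberg adjustment within the comparison.
#' Genes with `avg_log2FC > logfc_min` are returned, sorted by descending
#' fold change.
#'
#' @param x normalized matrix from [normalize_counts()].
#' @param counts matching [cell_counts()] (detection fractions use raw
#'   zero patterns).
#' @param labels per-cell cluster labels; defaults to those in `counts`.
#' @param group_A cluster name(s) forming the focal group.
#' @param group_B cluster name(s) to compare against, or `"rest"`.
#' @param min_pct detection-fraction floor for testing a gene.
#' @param logfc_min fold-change threshold; use `-Inf` to keep all tested
#'   genes.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return A data.frame (`marker_table`) with columns `gene`, `cluster_A`,
#'   `cluster_B`, `avg_log2FC`, `p_value`, `p_adj`, `pct_A`, `pct_B`.
#' @export
find_markers <- function(x, counts, labels = NULL, group_A, group_B = "rest",
                         min_pct = 0.25, logfc_min = 0.25,
                         test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  stopifnot(inherits(counts, "cell_counts"))
  if (is.null(labels)) labels <- counts$cell_meta$cluster
  in_A <- labels %in% group_A
  in_B <- if (identical(group_B, "rest")) !in_A else labels %in% group_B
  if (sum(in_A) < 3L || sum(in_B) < 3L) {
    stop("each group needs at least 3 cells")
  }
  raw <- counts$counts
  pct_A <- Matrix::colSums(raw[in_A, , drop = FALSE] > 0) / sum(in_A)
  pct_B <- Matrix::colSums(raw[in_B, , drop = FALSE] > 0) / sum(in_B)
  tested <- pmax(pct_A, pct_B) >= min_pct
  if (!any(tested)) {
    return(empty_marker_table(group_A, group_B))
  }
  xa <- as.matrix(x[in_A, tested, drop = FALSE])
  xb <- as.matrix(x[in_B, tested, drop = FALSE])
  mean_A <- colMeans(expm1(xa))
  mean_B <- colMeans(expm1(xb))
  lfc <- log2((mean_A + 1) / (mean_B + 1))
  p <- if (test == "wilcoxon") wilcox_vec(xa, xb) else t_vec(xa, xb)
  tab <- data.frame(
    gene = colnames(x)[tested],
    cluster_A = paste(group_A, collapse = "+"),
    cluster_B = if (identical(group_B, "rest")) "rest"
                else paste(group_B, collapse = "+"),
    avg_log2FC = lfc,
    p_value = p,
    p_adj = p.adjust(p, method = "BH"),
    pct_A = pct_A[tested],
    pct_B = pct_B[tested],
    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[tab$avg_log2FC > logfc_min, , drop = FALSE]
  tab <- tab[order(-tab$avg_log2FC), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("marker_table", "data.frame")
  tab
}

empty_marker_table <- function(group_A, group_B) {
  tab <- data.frame(gene = character(0), cluster_A = character(0),
                    cluster_B = character(0), avg_log2FC = numeric(0),
                    p_value = numeric(0), p_adj = numeric(0),
                    pct_A = numeric(0), pct_B = numeric(0),
                    stringsAsFactors = FALSE)
  class(tab) <- c("marker_table", "data.frame")
  tab
}

# vectorized two-sided Wilcoxon rank-sum, normal approximation with tie
# correction and continuity correction (columns = genes)
wilcox_vec <- function(xa, xb) {
  n1 <- nrow(xa); n2 <- nrow(xb); n <- n1 + n2
  vapply(seq_len(ncol(xa)), function(j) {
    v <- c(xa[, j], xb[, j])
    r <- rank(v)
    W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U for A
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- (n1 * n2 / 12) * (n + 1 - tie_term)
    if (sigma2 <= 0) return(1)
    z <- W - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    2 * pnorm(-abs(z))
  }, numeric(1))
}

# Welch two-sample t-test p-values per column
t_vec <- function(xa, xb) {
  n1 <- nrow(xa); n2 <- nrow(xb)
  m1 <- colMeans(xa); m2 <- colMeans(xb)
  v1 <- apply(xa, 2, var); v2 <- apply(xb, 2, var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[!is.finite(p)] <- 1
  p
}

#' Genes specifically and jointly expressed by a focal cluster pair
#'
#' Merges the two focal clusters into one group and finds genes enriched in
#' the merged group against all remaining cells at a stringent fold-change
#' threshold (default `avg_log2FC > 3`) — the shared gene program of the
#' pair.
#'
#' @param x,counts,labels as in [find_markers()].
#' @param focal_pair character vector of exactly two distinct cluster names.
#' @param logfc_min fold-change threshold (default 3).
#' @param ... passed to [find_markers()].
#' @return A `marker_table` (see [find_markers()]).
#' @export
shared_program <- function(x, counts, labels = NULL, focal_pair,
                           logfc_min = 3.0, ...) {
  if (length(focal_pair) != 2L || focal_pair[1] == focal_pair[2]) {
    stop("focal_pair must name two distinct clusters")
  }
  if (is.null(labels)) labels <- counts$cell_meta$cluster
  if (!all(focal_pair %in% labels)) stop("both focal clusters must be present")
  find_markers(x, counts, labels, group_A = focal_pair, group_B = "rest",
               logfc_min = logfc_min, ...)
}

#' Fraction of a shared gene program belonging to a category
#'
#' @param shared a `marker_table` (e.g. from [shared_program()]).
#' @param category a gene set: character vector or one element of
#'   [read_gmt()].
#' @return List with `fraction` = |shared ∩ category| / |shared|, plus the
#'   intersection and the shared gene list.
#' @export
category_fraction <- function(shared, category) {
  genes <- unique(if (is.data.frame(shared)) shared$gene else shared)
  if (length(genes) == 0L) stop("shared gene table is empty")
  category <- unique(unlist(category, use.names = FALSE))
  inter <- intersect(genes, category)
  list(fraction = length(inter) / length(genes),
       in_category = inter, shared_genes = genes)
}

#' Per-cell gene-set score
#'
#' Mean normalized expression over the set genes minus the mean over a
#' size-matched control set drawn from the same average-expression bins
#' (default 25 bins), so the score is centred near zero for a random set.
#'
#' @param x normalized matrix from [normalize_counts()].
#' @param gene_set character vector of gene ids (>= 1 present in `x`).
#' @param n_bins number of mean-expression bins for control matching.
#' @param seed RNG seed for control sampling.
#' @return Named numeric vector of per-cell scores.
#' @export
score_gene_set <- function(x, gene_set, n_bins = 25L, seed = 1L) {
  set_genes <- unique(gene_set)
  set_genes <- set_genes[set_genes %in% colnames(x)]
  if (length(set_genes) == 0L) stop("no gene of the set is present")
  gene_means <- Matrix::colMeans(x)
  bins <- cut(rank(gene_means, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- colnames(x)
  set.seed(seed)
  ctrl <- unlist(lapply(set_genes, function(g) {
    pool <- names(bins)[bins == bins[[g]]]
    sample(pool, 1L)
  }))
  set_score <- Matrix::rowMeans(x[, set_genes, drop = FALSE])
  ctrl_score <- Matrix::rowMeans(x[, ctrl, drop = FALSE])
  setNames(as.numeric(set_score - ctrl_score), rownames(x))
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (unique gene ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(ln, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(ln) strsplit(ln, "\t")[[1]][1],
                        character(1), USE.NAMES = FALSE)
  sets
}

#' Write a marker table as TSV
#'
#' @param tab a `marker_table`.
#' @param path output path.
#' @export
write_marker_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
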