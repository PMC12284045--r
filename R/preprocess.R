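#' Raw single-cell count container
#'
#' Holds a sparse cells x genes raw count matrix with per-cell metadata:
#' cluster label, optional batch, total counts (`n_umi`), detected genes
#' (`n_genes`) and percent mitochondrial counts (`pct_mito`, genes matched
#' by name prefix, default `"mt-"` case-insensitive).
#'
#' @param counts sparse (or dense) non-negative integer matrix, cells in
#'   rows, genes in columns, with dimnames.
#' @param cluster per-cell cluster label (character, no empty strings).
#' @param batch optional per-cell batch label.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return An object of class `cell_counts`: list with `counts` (dgCMatrix)
#'   and `cell_meta` (data.frame).
#' @export
cell_counts <- function(counts, cluster, batch = NULL, mito_prefix = "mt-") {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs cell ids (rownames) and gene ids (colnames)")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene ids")
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop("counts must be non-negative integers")
  }
  cluster <- as.character(cluster)
  if (length(cluster) != nrow(counts) || any(is.na(cluster) | cluster == "")) {
    stop("`cluster` must be a non-empty label for every cell")
  }
  n_umi <- Matrix::rowSums(counts)
  n_genes <- Matrix::rowSums(counts > 0)
  mito <- grepl(paste0("^", mito_prefix), colnames(counts), ignore.case = TRUE)
  pct_mito <- if (any(mito)) {
    100 * Matrix::rowSums(counts[, mito, drop = FALSE]) / pmax(n_umi, 1)
  } else rep(0, nrow(counts))
  meta <- data.frame(cell_id = rownames(counts), cluster = cluster,
                     n_umi = as.numeric(n_umi), n_genes = as.integer(n_genes),
                     pct_mito = as.numeric(pct_mito),
                     stringsAsFactors = FALSE, row.names = rownames(counts))
  if (!is.null(batch)) meta$batch <- as.character(batch)
  structure(list(counts = counts, cell_meta = meta), class = "cell_counts")
}

#' @method print cell_counts
#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("cell_counts: %d cells x %d genes, %d clusters\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$cluster))))
  invisible(x)
}

#' Quality-control thresholds
#'
#' Defaults follow common practice for adult-eye droplet data: 500-20,000
#' UMIs, 800-6,000 detected genes, complexity `log10(n_genes)/log10(n_umi)`
#' above 0.8, and under 10 percent mitochondrial counts.
#'
#' @param umi_min,umi_max total-count bounds (inclusive).
#' @param genes_min,genes_max detected-gene bounds (inclusive).
#' @param complexity_min lower bound (exclusive) on
#'   `log10(n_genes)/log10(n_umi)`, in (0, 1].
#' @param mito_max upper bound (exclusive) on percent mitochondrial counts.
#' @return A validated list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(umi_min = 500, umi_max = 20000, genes_min = 800,
                          genes_max = 6000, complexity_min = 0.8,
                          mito_max = 10) {
  if (!(umi_min < umi_max)) stop("umi_min must be < umi_max")
  if (!(genes_min < genes_max)) stop("genes_min must be < genes_max")
  if (!(complexity_min > 0 && complexity_min <= 1)) {
    stop("complexity_min must lie in (0, 1]")
  }
  if (mito_max < 0 || mito_max > 100) stop("mito_max must lie in [0, 100]")
  structure(list(umi_min = umi_min, umi_max = umi_max, genes_min = genes_min,
                 genes_max = genes_max, complexity_min = complexity_min,
                 mito_max = mito_max), class = "qc_thresholds")
}

#' Filter cells (and sparsely detected genes) by quality criteria
#'
#' Retains cells with `umi_min <= n_umi <= umi_max`,
#' `genes_min <= n_genes <= genes_max`,
#' `log10(n_genes)/log10(n_umi) > complexity_min` and
#' `pct_mito < mito_max`. Optionally drops genes detected in fewer than
#' `gene_min_cells` retained cells. The number of cells removed by each
#' criterion is reported and attached as attribute `qc_report`.
#'
#' @param counts a [cell_counts()] object.
#' @param thresholds a [qc_thresholds()] object.
#' @param gene_min_cells minimum retained cells a gene must be detected in
#'   (default 3); `0` disables gene filtering.
#' @param quiet suppress the per-criterion report.
#' @return The filtered [cell_counts()] object.
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds(),
                      gene_min_cells = 3L, quiet = FALSE) {
  stopifnot(inherits(counts, "cell_counts"), inherits(thresholds, "qc_thresholds"))
  m <- counts$cell_meta
  complexity <- log10(pmax(m$n_genes, 1)) / log10(pmax(m$n_umi, 2))
  fail <- list(
    umi  = m$n_umi < thresholds$umi_min | m$n_umi > thresholds$umi_max,
    genes = m$n_genes < thresholds$genes_min | m$n_genes > thresholds$genes_max,
    complexity = complexity <= thresholds$complexity_min,
    mito = m$pct_mito >= thresholds$mito_max)
  removed <- vapply(fail, function(z) sum(z), integer(1))
  keep <- !Reduce(`|`, fail)
  if (!any(keep)) {
    stop(sprintf(
      "all %d cells removed by QC (umi: %d, genes: %d, complexity: %d, mito: %d)",
      nrow(m), removed["umi"], removed["genes"], removed["complexity"],
      removed["mito"]))
  }
  sub <- counts$counts[keep, , drop = FALSE]
  genes_removed <- 0L
  if (gene_min_cells > 0L) {
    gkeep <- Matrix::colSums(sub > 0) >= gene_min_cells
    genes_removed <- sum(!gkeep)
    sub <- sub[, gkeep, drop = FALSE]
  }
  if (!quiet) {
    message(sprintf(
      "qc_filter: kept %d/%d cells (removed umi=%d genes=%d complexity=%d mito=%d); dropped %d genes detected in < %d cells",
      sum(keep), nrow(m), removed["umi"], removed["genes"],
      removed["complexity"], removed["mito"], genes_removed, gene_min_cells))
  }
  out <- cell_counts(sub, cluster = m$cluster[keep],
                     batch = if ("batch" %in% names(m)) m$batch[keep])
  attr(out, "qc_report") <- c(as.list(removed),
                              list(genes_removed = genes_removed,
                                   cells_kept = sum(keep)))
  out
}

#' Depth-normalize and log-transform counts
#'
#' Scales each cell's total to `scale` (default 10,000) counts and applies
#' `log1p`: `x = ln(1 + scale * c / total)`. Sparse zeros are preserved.
#'
#' @param counts a [cell_counts()] object; every cell must have > 0 counts.
#' @param scale library-size target.
#' @return A sparse cells x genes `dgCMatrix` of normalized values with
#'   attribute `scale`.
#' @export
normalize_counts <- function(counts, scale = 10000) {
  stopifnot(inherits(counts, "cell_counts"))
  tot <- counts$cell_meta$n_umi
  if (any(tot == 0)) {
    stop(sprintf("cell(s) with zero counts: %s",
                 paste(utils::head(rownames(counts$counts)[tot == 0], 5),
                       collapse = ", ")))
  }
  x <- counts$counts
  # dgCMatrix is column-compressed: x@i holds 0-based row (cell) indices
  x@x <- log1p(scale * x@x / tot[x@i + 1L])
  attr(x, "scale") <- scale
  x
}

#' Per-cluster expression profiles
#'
#' Computes, per cluster: the mean normalized expression of every gene, the
#' fraction of cells with raw count > 0 (detection fraction), and the cell
#' count.
#'
#' @param x normalized matrix from [normalize_counts()].
#' @param counts the matching [cell_counts()] object (zero patterns come
#'   from raw counts).
#' @param labels per-cell cluster labels; defaults to the labels stored in
#'   `counts`.
#' @return An object of class `cluster_profile`: list with `mean_expr`,
#'   `frac_expr` (clusters x genes) and `n_cells`.
#' @export
cluster_profiles <- function(x, counts, labels = NULL) {
  stopifnot(inherits(counts, "cell_counts"))
  if (is.null(labels)) labels <- counts$cell_meta$cluster
  if (length(labels) != nrow(x)) stop("labels must cover all cells")
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  n_cells <- vapply(groups, function(g) sum(labels == g), numeric(1))
  fac <- factor(labels, levels = groups)
  ind <- Matrix::sparseMatrix(i = as.integer(fac), j = seq_along(labels),
                              x = 1, dims = c(length(groups), length(labels)))
  mean_expr <- as.matrix(ind %*% x) / n_cells
  frac_expr <- as.matrix(ind %*% (counts$counts > 0)) / n_cells
  dimnames(mean_expr) <- list(groups, colnames(x))
  dimnames(frac_expr) <- list(groups, colnames(counts$counts))
  structure(list(mean_expr = mean_expr, frac_expr = frac_expr,
                 n_cells = setNames(n_cells, groups)),
            class = "cluster_profile")
}

#' @method print cluster_profile
#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("cluster_profile: %d clusters x %d genes\n",
              nrow(x$mean_expr), ncol(x$mean_expr)))
  print(x$n_cells)
  invisible(x)
}

#' Restrict a matrix to a gene list
#'
#' Keeps the columns present in `gene_list`, in the list's order; reports
#' genes not found. Works on normalized or raw matrices.
#'
#' @param x matrix with gene columns.
#' @param gene_list character vector (duplicates deduplicated with warning).
#' @param quiet suppress the not-found report.
#' @return The column-restricted matrix.
#' @export
restrict_genes <- function(x, gene_list, quiet = FALSE) {
  if (length(gene_list) == 0L) stop("gene_list is empty")
  if (anyDuplicated(gene_list)) {
    warning("duplicate names in gene_list; deduplicated")
    gene_list <- unique(gene_list)
  }
  found <- gene_list[gene_list %in% colnames(x)]
  if (length(found) == 0L) stop("no gene of gene_list is present in the matrix")
  if (!quiet && length(found) < length(gene_list)) {
    message(sprintf("restrict_genes: %d/%d genes not found",
                    length(gene_list) - length(found), length(gene_list)))
  }
  x[, found, drop = FALSE]
}

# ---- 10x-style I/O ---------------------------------------------------------

#' Read / write a MatrixMarket count triple with cluster labels
#'
#' `read_count_matrix` reads `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and
#' `labels.tsv` (two columns: cell_id, cluster) from a directory. The
#' matrix orientation is auto-detected from the dimensions: if rows match
#' the gene list (10x convention, genes x cells) the matrix is transposed
#' to cells x genes.
#'
#' @param dir directory holding the four files.
#' @param mito_prefix passed to [cell_counts()].
#' @return A [cell_counts()] object.
#' @name count_matrix_io
#' @export
read_count_matrix <- function(dir, mito_prefix = "mt-") {
  mtx <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  genes <- vapply(strsplit(genes, "\t"), `[`, character(1), 1L)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(mtx) == length(genes) && ncol(mtx) == length(barcodes)) {
    mtx <- Matrix::t(mtx)
  } else if (!(nrow(mtx) == length(barcodes) && ncol(mtx) == length(genes))) {
    stop("matrix dimensions match neither genes x cells nor cells x genes")
  }
  dimnames(mtx) <- list(barcodes, genes)
  lab <- utils::read.delim(file.path(dir, "labels.tsv"),
                           header = TRUE, stringsAsFactors = FALSE)
  cl <- setNames(as.character(lab[[2]]), lab[[1]])[barcodes]
  cell_counts(mtx, cluster = cl, mito_prefix = mito_prefix)
}

#' @rdname count_matrix_io
#' @param counts a [cell_counts()] object to write.
#' @export
write_count_matrix <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(counts$counts), file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts$counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(counts$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(cell_id = rownames(counts$counts),
               cluster = counts$cell_meta$cluster),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
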