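#' Correlation/Ward dendrogram of cell types from expression profiles
#'
#' Pairwise distance `d(u, v) = 1 - Pearson(mean_expr_u, mean_expr_v)`
#' between cluster mean-expression profiles, clustered with Ward's linkage.
#' Correlations use the sample formula over genes; a cluster with zero
#' variance across the selected genes is an error (its correlation is
#' undefined).
#'
#' @param profile a [cluster_profiles()] object.
#' @param genes `"all"` or a character vector of genes to use.
#' @return An `hclust` object with attributes `metric = "correlation"` and
#'   `linkage`.
#' @export
expression_dendrogram <- function(profile, genes = "all") {
  stopifnot(inherits(profile, "cluster_profile"))
  m <- profile$mean_expr
  if (!identical(genes, "all")) m <- restrict_genes(m, genes, quiet = TRUE)
  if (nrow(m) < 2L) stop("need at least 2 clusters")
  if (ncol(m) < 2L) stop("need at least 2 genes")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance profile for cluster(s): %s",
                 paste(rownames(m)[sds == 0], collapse = ", ")))
  }
  d <- stats::as.dist(1 - cor(t(m)))
  hc <- hclust(d, method = "ward.D2")
  attr(hc, "metric") <- "correlation"
  attr(hc, "linkage") <- "ward.D2"
  hc
}

#' Chromatin-accessibility peak matrix
#'
#' @param counts sparse cells x peaks count (or binary) matrix with
#'   dimnames; peak ids must match `peaks$id`.
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `id` (default `chrom:start-end`).
#' @param cell_types per-cell type labels.
#' @return An object of class `peak_matrix`.
#' @export
peak_matrix <- function(counts, peaks, cell_types) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (!all(c("chrom", "start", "end") %in% names(peaks))) {
    stop("peaks need chrom, start, end")
  }
  if (is.null(peaks$id)) {
    peaks$id <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  }
  if (any(peaks$start >= peaks$end)) stop("peak start must be < end")
  if (anyDuplicated(peaks$id)) stop("duplicate peak ids")
  if (ncol(counts) != nrow(peaks)) stop("counts/peaks dimension mismatch")
  colnames(counts) <- peaks$id
  if (length(cell_types) != nrow(counts)) {
    stop("cell_types must cover all cells")
  }
  structure(list(counts = counts, peaks = peaks,
                 cell_types = as.character(cell_types)),
            class = "peak_matrix")
}

#' @method print peak_matrix
#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("peak_matrix: %d cells x %d peaks, %d cell types\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cell_types))))
  invisible(x)
}

#' Keep peaks detected in a minimum fraction of cells
#'
#' @param pm a [peak_matrix()].
#' @param min_cell_frac detection-fraction threshold (inclusive; a peak in
#'   exactly that fraction of cells is kept). Default 0.01.
#' @return The filtered [peak_matrix()].
#' @export
filter_peaks <- function(pm, min_cell_frac = 0.01) {
  stopifnot(inherits(pm, "peak_matrix"))
  frac <- Matrix::colSums(pm$counts > 0) / nrow(pm$counts)
  keep <- frac >= min_cell_frac
  if (!any(keep)) stop("all peaks removed by the cell-fraction filter")
  peak_matrix(pm$counts[, keep, drop = FALSE],
              pm$peaks[keep, , drop = FALSE], pm$cell_types)
}

#' Read a BED file (3 or 6 columns)
#'
#' 0-based half-open intervals; strand required when `need_strand`.
#' Malformed lines raise an error naming the line number.
#'
#' @param path BED file path.
#' @param need_strand require a valid strand column.
#' @return data.frame with chrom, start, end, (name, score, strand).
#' @export
read_bed <- function(path, need_strand = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  n_fields <- lengths(parts)
  min_fields <- if (need_strand) 6L else 3L
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < min_fields ||
        is.na(suppressWarnings(as.integer(p[2]))) ||
        is.na(suppressWarnings(as.integer(p[3]))) ||
        as.integer(p[2]) >= as.integer(p[3]) ||
        (need_strand && !p[6] %in% c("+", "-"))) {
      stop(sprintf("malformed BED line %d in %s", i, path))
    }
  }
  df <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    start = as.integer(vapply(parts, `[`, character(1), 2L)),
    end = as.integer(vapply(parts, `[`, character(1), 3L)),
    stringsAsFactors = FALSE)
  if (all(n_fields >= 6L)) {
    df$name <- vapply(parts, `[`, character(1), 4L)
    df$strand <- vapply(parts, `[`, character(1), 6L)
  }
  df
}

bed_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
}

#' Remove peaks overlapping promoters or gene bodies
#'
#' Promoter windows span `upstream` bases before to `downstream` bases
#' after each TSS, strand-aware (flipped on the minus strand). Any peak
#' sharing at least one base with a promoter window or a gene-body interval
#' is removed, leaving distal intergenic peaks.
#'
#' @param pm a [peak_matrix()].
#' @param tss_bed BED6 path (or data.frame from [read_bed()]) of TSS
#'   positions with strand.
#' @param gene_bed BED path (or data.frame) of gene bodies incl. introns.
#' @param upstream,downstream promoter window, default 2000/200.
#' @return The filtered [peak_matrix()].
#' @export
exclude_promoter_and_genic <- function(pm, tss_bed, gene_bed,
                                       upstream = 2000L, downstream = 200L) {
  stopifnot(inherits(pm, "peak_matrix"))
  tss <- if (is.character(tss_bed)) read_bed(tss_bed, need_strand = TRUE) else tss_bed
  genes <- if (is.character(gene_bed)) read_bed(gene_bed) else gene_bed
  tss_gr <- bed_to_granges(tss)
  # anchor at the TSS (strand-aware 5' end), then expand to the window
  tss_gr <- GenomicRanges::resize(tss_gr, width = 1L, fix = "start")
  prom <- GenomicRanges::promoters(tss_gr, upstream = upstream,
                                   downstream = downstream)
  gene_gr <- bed_to_granges(genes)
  peaks_gr <- bed_to_granges(pm$peaks)
  hit <- IRanges::overlapsAny(peaks_gr, prom, ignore.strand = TRUE) |
         IRanges::overlapsAny(peaks_gr, gene_gr, ignore.strand = TRUE)
  if (all(hit)) stop("all peaks overlap promoters or gene bodies")
  peak_matrix(pm$counts[, !hit, drop = FALSE],
              pm$peaks[!hit, , drop = FALSE], pm$cell_types)
}

#' TF-IDF weighting and LSI embedding of a peak matrix
#'
#' Cells are documents and peaks terms: `tf = c_ij / sum_j c_ij`,
#' `idf_j = N_cells / n_cells_detecting_peak_j`, and the weighted value is
#' `ln(1 + scale * tf * idf)`. A truncated SVD of the weighted matrix gives
#' the embedding; component 1, typically depth-correlated, is dropped by
#' default (`component_range` starting at 2).
#'
#' @param pm a filtered [peak_matrix()]; every cell needs >= 1 peak.
#' @param n_components last SVD component retained (default 30).
#' @param scale TF-IDF scale constant (default 10,000).
#' @param drop_first drop component 1 from the embedding.
#' @return An object of class `lsi_embedding`: list with `coords` (cells x
#'   retained components), `d` (singular values), `component_range`,
#'   `cell_types`.
#' @export
tfidf_lsi <- function(pm, n_components = 30L, scale = 10000, drop_first = TRUE) {
  stopifnot(inherits(pm, "peak_matrix"))
  tot <- Matrix::rowSums(pm$counts)
  if (any(tot == 0)) {
    stop(sprintf("cell(s) with zero peaks: %s",
                 paste(utils::head(rownames(pm$counts)[tot == 0], 5),
                       collapse = ", ")))
  }
  tfidf <- tfidf_weight(pm$counts, scale = scale)
  n_components <- min(n_components, nrow(tfidf) - 1L, ncol(tfidf) - 1L)
  sv <- svd(as.matrix(tfidf), nu = n_components, nv = 0L)
  coords <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(coords) <- rownames(pm$counts)
  colnames(coords) <- paste0("LSI", seq_len(n_components))
  first <- if (drop_first) 2L else 1L
  if (first > n_components) stop("not enough components")
  range <- first:n_components
  structure(list(coords = coords[, range, drop = FALSE],
                 d = sv$d[seq_len(n_components)],
                 component_range = range,
                 cell_types = pm$cell_types),
            class = "lsi_embedding")
}

# TF-IDF weighted sparse matrix; zeros stay zero
tfidf_weight <- function(counts, scale = 10000) {
  tot <- Matrix::rowSums(counts)
  n_detect <- Matrix::colSums(counts > 0)
  idf <- nrow(counts) / pmax(n_detect, 1)
  x <- counts
  j <- rep.int(seq_len(ncol(x)), diff(x@p))
  x@x <- log1p(scale * (x@x / tot[x@i + 1L]) * idf[j])
  x
}

#' Hierarchical tree of cell-type centroids in an embedding
#'
#' Centroids are coordinate-wise means per cell type; pairwise distances
#' use one of four metrics (euclidean, maximum/Chebyshev, manhattan,
#' canberra — 0/0 Canberra terms contribute 0), clustered with the chosen
#' linkage (default complete).
#'
#' @param embedding an [tfidf_lsi()] result, or a numeric cells x dims
#'   matrix.
#' @param labels per-cell type labels; defaults to those in the embedding.
#' @param metric one of `"euclidean"`, `"maximum"`, `"manhattan"`,
#'   `"canberra"`.
#' @param linkage `hclust` method, default `"complete"`.
#' @return An `hclust` object with `metric` and `linkage` attributes.
#' @export
centroid_distance_tree <- function(embedding, labels = NULL,
                                   metric = c("euclidean", "maximum",
                                              "manhattan", "canberra"),
                                   linkage = "complete") {
  metric <- match.arg(metric)
  coords <- if (inherits(embedding, "lsi_embedding")) embedding$coords
            else as.matrix(embedding)
  if (is.null(labels) && inherits(embedding, "lsi_embedding")) {
    labels <- embedding$cell_types
  }
  if (length(labels) != nrow(coords)) stop("labels must cover all cells")
  cents <- centroids(coords, labels)
  if (nrow(cents) < 2L) stop("need at least 2 cell types")
  # base dist() omits-and-rescales 0/0 Canberra terms; here they count as 0
  d <- if (metric == "canberra") canberra_dist(cents)
       else dist(cents, method = metric)
  hc <- hclust(d, method = linkage)
  attr(hc, "metric") <- metric
  attr(hc, "linkage") <- linkage
  hc
}

# Canberra distance with the 0/0-term-contributes-0 convention
canberra_dist <- function(m) {
  k <- nrow(m)
  out <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      num <- abs(m[i, ] - m[j, ])
      den <- abs(m[i, ]) + abs(m[j, ])
      term <- ifelse(den == 0, 0, num / den)
      out[i, j] <- out[j, i] <- sum(term)
    }
  }
  stats::as.dist(out)
}

centroids <- function(coords, labels) {
  groups <- sort(unique(as.character(labels)))
  out <- t(vapply(groups, function(g) {
    colMeans(coords[labels == g, , drop = FALSE])
  }, numeric(ncol(coords))))
  rownames(out) <- groups
  out
}

#' Export a dendrogram as Newick
#'
#' @param hc an `hclust` object.
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  tr <- ape::as.phylo(hc)
  s <- ape::write.tree(tr)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
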