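#' Pipeline configuration
#'
#' Collects the inputs and thresholds for the three analyses. Accepts a
#' nested list (e.g. parsed from YAML with [read_pipeline_config()]);
#' missing entries fall back to the documented defaults.
#'
#' @param counts_dir directory with matrix.mtx/genes.tsv/barcodes.tsv/
#'   labels.tsv.
#' @param tf_list path to a TF gene list (one id per line) or a character
#'   vector.
#' @param ... named overrides: `qc` (list passed to [qc_thresholds()]),
#'   `gene_min_cells`, `marker` (`min_pct`, `logfc_min`, `test`),
#'   `shared` (`focal_pair`, `logfc_min`), `category_gmt`, `presence_min`,
#'   `parsimony` (`method`, `outgroup`, `bootstrap`), `dendrogram`
#'   (`metric`, `linkage`), `phylostratum_map`, `marker_tables`,
#'   `min_stratum`, `peaks_dir`, `tss_bed`, `gene_bed`, `min_cell_frac`,
#'   `n_components`, `da` (`logfc_min`, `p_adj_max`), `seed`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_dir = NULL, tf_list = NULL, ...) {
  cfg <- utils::modifyList(default_pipeline_config(),
                           c(list(counts_dir = counts_dir, tf_list = tf_list),
                             list(...)))
  class(cfg) <- "pipeline_config"
  cfg
}

default_pipeline_config <- function() {
  list(
    counts_dir = NULL, tf_list = NULL,
    qc = list(), gene_min_cells = 3L,
    marker = list(min_pct = 0.25, logfc_min = 0.25, test = "wilcoxon"),
    shared = list(focal_pair = NULL, logfc_min = 3.0),
    category_gmt = NULL,
    presence_min = 0.10,
    parsimony = list(method = "auto", outgroup = NULL, bootstrap = 0L),
    dendrogram = list(metric = "euclidean", linkage = "complete"),
    phylostratum_map = NULL, marker_tables = NULL, min_stratum = 10L,
    peaks_dir = NULL, tss_bed = NULL, gene_bed = NULL,
    min_cell_frac = 0.01, n_components = 30L,
    da = list(logfc_min = 2.0, p_adj_max = 0.05),
    seed = 1L)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()]. Referenced input
#'   files are checked for existence.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_pipeline_config(), raw)
  class(cfg) <- "pipeline_config"
  validate_config_paths(cfg)
  cfg
}

validate_config_paths <- function(cfg) {
  paths <- c(cfg$counts_dir, cfg$category_gmt, cfg$phylostratum_map,
             cfg$marker_tables, cfg$peaks_dir, cfg$tss_bed, cfg$gene_bed,
             if (is.character(cfg$tf_list) && length(cfg$tf_list) == 1L &&
                 file.exists(cfg$tf_list)) NULL)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  invisible(cfg)
}

write_manifest <- function(cfg, out_dir, outputs) {
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(serializable_config(unclass(cfg)), cfg_file,
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   seed = cfg$seed, outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

# in-memory objects passed through the config are represented by their
# class in the recorded manifest (files are recorded by path)
serializable_config <- function(x) {
  if (is.object(x)) return(sprintf("<in-memory %s>", class(x)[1]))
  if (is.list(x)) return(lapply(x, serializable_config))
  x
}

load_tf_list <- function(tf_list) {
  if (is.character(tf_list) && length(tf_list) == 1L && file.exists(tf_list)) {
    readLines(tf_list)
  } else as.character(tf_list)
}

#' Run the cell-type homology analysis
#'
#' QC -> normalization -> per-cluster markers -> (optional) shared program
#' of a focal pair with category fraction -> TF character matrix ->
#' maximum-parsimony tree(s) with strict consensus and optional bootstrap
#' -> correlation/Ward expression dendrogram. All tables are TSV, all trees
#' Newick; a JSON manifest records the config hash and seed.
#'
#' @param config a [pipeline_config()] with `counts_dir` and `tf_list` set,
#'   or a path to a YAML config.
#' @param out_dir output directory.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_homology_analysis <- function(config, out_dir) {
  cfg <- as_pipeline_config(config)
  if (is.null(cfg$counts_dir) || is.null(cfg$tf_list)) {
    stop("config must provide counts_dir and tf_list")
  }
  validate_config_paths(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  counts <- stage("read", read_count_matrix(cfg$counts_dir))
  qc <- stage("qc", qc_filter(counts, do.call(qc_thresholds, cfg$qc),
                              gene_min_cells = cfg$gene_min_cells,
                              quiet = TRUE))
  jsonlite::write_json(attr(qc, "qc_report"),
                       file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  x <- stage("normalize", normalize_counts(qc))
  prof <- stage("profiles", cluster_profiles(x, qc))

  clusters <- rownames(prof$mean_expr)
  markers <- stage("markers", lapply(clusters, function(cl) {
    find_markers(x, qc, group_A = cl, min_pct = cfg$marker$min_pct,
                 logfc_min = cfg$marker$logfc_min, test = cfg$marker$test)
  }))
  names(markers) <- clusters
  marker_tab <- do.call(rbind, markers)
  write_marker_table(marker_tab, file.path(out_dir, "markers.tsv"))

  shared <- NULL; cat_frac <- NULL
  if (!is.null(cfg$shared$focal_pair)) {
    shared <- stage("shared_program",
                    shared_program(x, qc, focal_pair = cfg$shared$focal_pair,
                                   logfc_min = cfg$shared$logfc_min,
                                   min_pct = cfg$marker$min_pct,
                                   test = cfg$marker$test))
    write_marker_table(shared, file.path(out_dir, "shared_program.tsv"))
    if (!is.null(cfg$category_gmt)) {
      sets <- read_gmt(cfg$category_gmt)
      cat_frac <- category_fraction(shared, sets[[1]])
      jsonlite::write_json(cat_frac, file.path(out_dir, "category_fraction.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
  }

  tfs <- load_tf_list(cfg$tf_list)
  cm <- stage("characters", filter_informative(
    binarize_characters(prof, tfs, presence_min = cfg$presence_min),
    quiet = TRUE))
  write_character_matrix(cm, file.path(out_dir, "character_matrix.tsv"))

  res <- stage("parsimony",
               search_mp_tree(cm, method = cfg$parsimony$method,
                              outgroup = cfg$parsimony$outgroup,
                              seed = cfg$seed))
  ape::write.tree(res$trees[[1]], file.path(out_dir, "mp_tree.nwk"))
  cons <- strict_consensus(res$trees)
  ape::write.tree(cons, file.path(out_dir, "mp_consensus.nwk"))
  boot <- NULL
  if (cfg$parsimony$bootstrap > 0L) {
    boot <- stage("bootstrap", bootstrap_support(cm, B = cfg$parsimony$bootstrap,
                                                 seed = cfg$seed,
                                                 method = cfg$parsimony$method))
    ape::write.tree(boot, file.path(out_dir, "mp_bootstrap.nwk"))
  }

  dend <- stage("dendrogram", expression_dendrogram(prof))
  writeLines(dendrogram_newick(dend), file.path(out_dir, "expression_dendrogram.nwk"))

  outputs <- list.files(out_dir)
  write_manifest(cfg, out_dir, outputs)
  invisible(list(qc = qc, profiles = prof, markers = marker_tab,
                 shared = shared, category_fraction = cat_frac,
                 character_matrix = cm, search = res, consensus = cons,
                 bootstrap = boot, dendrogram = dend))
}

as_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    return(read_pipeline_config(config))
  }
  if (is.list(config)) {
    cfg <- utils::modifyList(default_pipeline_config(), config)
    class(cfg) <- "pipeline_config"
    return(cfg)
  }
  stop("config must be a pipeline_config, list, or YAML path")
}

#' Run the phylostratigraphy analysis
#'
#' Maps marker gene sets onto phylostrata: per-set age distributions,
#' young-gene selections at the configured boundary, and a hypergeometric
#' young-gene enrichment of each set against the union background.
#'
#' @param config a [pipeline_config()] (or list/YAML path) with
#'   `phylostratum_map` (TSV path or `phylostratum_map` object) and
#'   `marker_tables` (named list of gene vectors, or a directory of
#'   marker TSVs).
#' @param out_dir output directory.
#' @return Invisibly, list of distributions, selections and enrichments.
#' @export
run_phylostrat_analysis <- function(config, out_dir) {
  cfg <- as_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  psmap <- if (inherits(cfg$phylostratum_map, "phylostratum_map")) {
    cfg$phylostratum_map
  } else read_phylostratum_map(cfg$phylostratum_map)
  sets <- cfg$marker_tables
  if (is.character(sets) && length(sets) == 1L && dir.exists(sets)) {
    files <- list.files(sets, pattern = "\\.tsv$", full.names = TRUE)
    sets <- lapply(files, function(f) utils::read.delim(f)$gene)
    names(sets) <- sub("\\.tsv$", "", basename(files))
  }
  if (is.null(sets) || length(sets) == 0L) stop("no marker gene sets provided")

  dists <- lapply(sets, assign_strata, psmap = psmap, quiet = TRUE)
  covered <- vapply(dists, function(d) d$total_mapped, numeric(1))
  if (all(covered == 0)) {
    warning("phylostratum map covers no marker genes")
  }
  young <- lapply(sets, select_young, psmap = psmap,
                  min_stratum = cfg$min_stratum)
  background <- unique(unlist(sets, use.names = FALSE))
  enrich <- lapply(sets, function(s) {
    tryCatch(young_gene_enrichment(s, background, psmap, cfg$min_stratum),
             error = function(e) list(odds_ratio = NA_real_, p_value = NA_real_,
                                      error = conditionMessage(e)))
  })
  dist_tab <- data.frame(
    set = rep(names(dists), each = psmap$n_strata),
    stratum = rep(seq_len(psmap$n_strata), length(dists)),
    n_genes = unlist(lapply(dists, function(d) unname(d$counts))))
  utils::write.table(dist_tab, file.path(out_dir, "age_distributions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  enrich_tab <- data.frame(
    set = names(enrich),
    odds_ratio = vapply(enrich, function(e) e$odds_ratio, numeric(1)),
    p_value = vapply(enrich, function(e) e$p_value, numeric(1)))
  utils::write.table(enrich_tab, file.path(out_dir, "young_gene_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(young)) {
    writeLines(young[[nm]], file.path(out_dir, paste0("young_", nm, ".txt")))
  }
  write_manifest(cfg, out_dir, list.files(out_dir))
  invisible(list(distributions = dists, young = young, enrichment = enrich))
}

#' Run the chromatin-accessibility analysis
#'
#' Peak-matrix filtering (cell-fraction floor, promoter/gene-body
#' exclusion), TF-IDF/LSI embedding, four-metric centroid dendrograms, and
#' a differentially-accessible peak table at the configured preset
#' (default avg_log2FC > 2, BH-adjusted p < 0.05).
#'
#' @param config a [pipeline_config()] (or list/YAML path) with
#'   `peaks_dir` (MatrixMarket triple + peaks.bed + labels.tsv),
#'   `tss_bed`, `gene_bed`.
#' @param out_dir output directory.
#' @return Invisibly, list with the filtered matrix, embedding,
#'   dendrograms and DA table.
#' @export
run_chromatin_analysis <- function(config, out_dir) {
  cfg <- as_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pm <- read_peak_matrix(cfg$peaks_dir)
  pm <- filter_peaks(pm, min_cell_frac = cfg$min_cell_frac)
  pm <- exclude_promoter_and_genic(pm, cfg$tss_bed, cfg$gene_bed)
  emb <- tfidf_lsi(pm, n_components = cfg$n_components)
  metrics <- c("euclidean", "maximum", "manhattan", "canberra")
  dends <- lapply(metrics, function(m) {
    centroid_distance_tree(emb, metric = m, linkage = cfg$dendrogram$linkage)
  })
  names(dends) <- metrics
  for (m in metrics) {
    writeLines(dendrogram_newick(dends[[m]]),
               file.path(out_dir, sprintf("chromatin_dendrogram_%s.nwk", m)))
  }
  da <- da_peaks(pm, logfc_min = cfg$da$logfc_min, p_adj_max = cfg$da$p_adj_max)
  write_marker_table(da, file.path(out_dir, "da_peaks.tsv"))
  stats_out <- list(n_cells = nrow(pm$counts), n_peaks = ncol(pm$counts),
                    cell_types = sort(unique(pm$cell_types)))
  jsonlite::write_json(stats_out, file.path(out_dir, "peak_stats.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_manifest(cfg, out_dir, list.files(out_dir))
  invisible(list(peak_matrix = pm, embedding = emb, dendrograms = dends,
                 da_peaks = da))
}

#' Differentially accessible peaks between each type and the rest
#'
#' Reuses the marker machinery on the peak matrix (peaks as genes) with
#' the stringent accessibility preset.
#'
#' @param pm a [peak_matrix()].
#' @param logfc_min fold-change threshold (default 2).
#' @param p_adj_max BH-adjusted p-value ceiling (default 0.05).
#' @param min_pct detection floor for testing a peak.
#' @return A `marker_table` over all cell types.
#' @export
da_peaks <- function(pm, logfc_min = 2.0, p_adj_max = 0.05, min_pct = 0.05) {
  cc <- cell_counts(pm$counts, cluster = pm$cell_types)
  x <- normalize_counts(cc)
  types <- sort(unique(pm$cell_types))
  tabs <- lapply(types, function(ty) {
    tab <- find_markers(x, cc, group_A = ty, min_pct = min_pct,
                        logfc_min = logfc_min)
    tab[tab$p_adj < p_adj_max, , drop = FALSE]
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Read a peak matrix from disk
#'
#' Expects `matrix.mtx` (peaks x cells or cells x peaks, auto-detected),
#' `peaks.bed`, `barcodes.tsv` and `labels.tsv` in `dir`.
#'
#' @param dir input directory.
#' @return A [peak_matrix()].
#' @export
read_peak_matrix <- function(dir) {
  mtx <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  peaks <- read_bed(file.path(dir, "peaks.bed"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(mtx) == nrow(peaks) && ncol(mtx) == length(barcodes)) {
    mtx <- Matrix::t(mtx)
  }
  rownames(mtx) <- barcodes
  lab <- utils::read.delim(file.path(dir, "labels.tsv"),
                           stringsAsFactors = FALSE)
  cl <- setNames(as.character(lab[[2]]), lab[[1]])[barcodes]
  peak_matrix(mtx, peaks, cl)
}

#' Write a peak matrix to disk
#'
#' @param pm a [peak_matrix()].
#' @param dir output directory.
#' @export
write_peak_matrix <- function(pm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(pm$counts), file.path(dir, "matrix.mtx"))
  bed <- pm$peaks
  utils::write.table(bed[, c("chrom", "start", "end")],
                     file.path(dir, "peaks.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(rownames(pm$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(data.frame(cell_id = rownames(pm$counts),
                                cell_type = pm$cell_types),
                     file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
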