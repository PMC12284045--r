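#' Gene-to-phylostratum map
#'
#' A phylostratum is an evolutionary age class: the oldest clade in which a
#' gene has detectable homologs, here an integer from 1 (last common
#' ancestor of cellular life) to `n_strata` (default 20, species-specific
#' genes). Genes absent from the map are tracked as unmapped.
#'
#' @param strata named integer vector, gene id -> stratum in
#'   `1..n_strata`.
#' @param unmapped genes known to the dataset but absent from the map.
#' @param n_strata number of strata (default 20).
#' @param map_source provenance string.
#' @return An object of class `phylostratum_map`.
#' @export
phylostratum_map <- function(strata, unmapped = character(0), n_strata = 20L,
                             map_source = NA_character_) {
  strata <- as.integer(round(strata)) |> setNames(names(strata))
  if (is.null(names(strata)) || any(!nzchar(names(strata)))) {
    stop("`strata` must be named by gene id")
  }
  if (any(strata < 1L | strata > n_strata)) {
    stop(sprintf("strata must lie in 1..%d", n_strata))
  }
  if (anyDuplicated(names(strata))) stop("duplicate genes in map")
  if (length(intersect(names(strata), unmapped))) {
    stop("a gene cannot be both mapped and unmapped")
  }
  structure(list(strata = strata, unmapped = unique(unmapped),
                 n_strata = as.integer(n_strata), map_source = map_source),
            class = "phylostratum_map")
}

#' @method print phylostratum_map
#' @export
print.phylostratum_map <- function(x, ...) {
  cat(sprintf("phylostratum_map: %d genes over %d strata (%d unmapped)\n",
              length(x$strata), x$n_strata, length(x$unmapped)))
  invisible(x)
}

#' Read / write a phylostratum map TSV (columns gene_id, stratum)
#'
#' @param path TSV path.
#' @param n_strata number of strata.
#' @name phylostratum_io
#' @export
read_phylostratum_map <- function(path, n_strata = 20L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "stratum") %in% names(tab))) {
    stop("phylostratum TSV needs columns gene_id, stratum")
  }
  phylostratum_map(setNames(tab$stratum, tab$gene_id), n_strata = n_strata,
                   map_source = path)
}

#' @rdname phylostratum_io
#' @param psmap a [phylostratum_map()] to write.
#' @export
write_phylostratum_map <- function(psmap, path) {
  utils::write.table(
    data.frame(gene_id = names(psmap$strata), stratum = psmap$strata),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Age distribution of a gene set
#'
#' Counts, per phylostratum, the genes of a set (set semantics: duplicates
#' counted once, with a warning). Genes absent from the map are listed as
#' unmapped and excluded from the counts.
#'
#' @param genes character vector of gene ids.
#' @param psmap a [phylostratum_map()].
#' @param quiet suppress the unmapped-genes warning.
#' @return An object of class `age_distribution`: list with `counts`
#'   (named integer vector over strata `1..n_strata`), `total_mapped`,
#'   `unmapped`.
#' @export
assign_strata <- function(genes, psmap, quiet = FALSE) {
  stopifnot(inherits(psmap, "phylostratum_map"))
  if (length(genes) == 0L) stop("gene list is empty")
  if (anyDuplicated(genes)) {
    if (!quiet) warning("duplicated genes in input; counted once")
    genes <- unique(genes)
  }
  mapped <- genes[genes %in% names(psmap$strata)]
  unmapped <- setdiff(genes, mapped)
  if (length(unmapped) && !quiet) {
    warning(sprintf("%d gene(s) not in the phylostratum map", length(unmapped)))
  }
  counts <- tabulate(psmap$strata[mapped], nbins = psmap$n_strata)
  names(counts) <- as.character(seq_len(psmap$n_strata))
  structure(list(counts = counts, total_mapped = length(mapped),
                 unmapped = unmapped, n_strata = psmap$n_strata),
            class = "age_distribution")
}

#' @method print age_distribution
#' @export
print.age_distribution <- function(x, ...) {
  cat(sprintf("age_distribution: %d mapped genes, %d unmapped\n",
              x$total_mapped, length(x$unmapped)))
  print(x$counts)
  invisible(x)
}

#' Select evolutionarily young genes
#'
#' Keeps genes whose stratum is `min_stratum` or higher (inclusive
#' boundary); stratum 10 marks the emergence of the vertebrate lineage on
#' the 20-level map, so the default selects vertebrate-and-younger genes.
#'
#' @param genes character vector.
#' @param psmap a [phylostratum_map()].
#' @param min_stratum inclusive lower bound (default 10).
#' @return Character vector of selected genes (mapped genes only).
#' @export
select_young <- function(genes, psmap, min_stratum = 10L) {
  stopifnot(inherits(psmap, "phylostratum_map"))
  genes <- unique(genes)
  mapped <- genes[genes %in% names(psmap$strata)]
  mapped[psmap$strata[mapped] >= min_stratum]
}

#' Hypergeometric enrichment of young genes in a set
#'
#' Tests whether genes at or above `min_stratum` are overrepresented in
#' `set_a` relative to `background` (one-sided hypergeometric upper tail on
#' the 2x2 table young/old x in-set/out-of-set). Only mapped genes enter
#' the table.
#'
#' @param set_a gene set, must be a subset of `background`.
#' @param background background gene universe.
#' @param psmap a [phylostratum_map()].
#' @param min_stratum inclusive "young" boundary (default 10).
#' @return List with `odds_ratio`, `p_value`, and the 2x2 `table`.
#' @export
young_gene_enrichment <- function(set_a, background, psmap,
                                  min_stratum = 10L) {
  set_a <- unique(set_a)
  background <- unique(background)
  if (!all(set_a %in% background)) stop("set_a must be a subset of background")
  if (length(background) < length(set_a)) stop("background smaller than set_a")
  bg <- background[background %in% names(psmap$strata)]
  sa <- set_a[set_a %in% bg]
  young_bg <- select_young(bg, psmap, min_stratum)
  if (length(young_bg) == 0L || length(young_bg) == length(bg)) {
    stop("degenerate table: no young (or no old) genes in the background")
  }
  a <- sum(sa %in% young_bg)                 # young, in set
  b <- length(sa) - a                        # old, in set
  c_ <- length(young_bg) - a                 # young, not in set
  d <- (length(bg) - length(young_bg)) - b   # old, not in set
  tab <- matrix(c(a, b, c_, d), 2, 2,
                dimnames = list(c("young", "old"), c("in_set", "out_of_set")))
  or <- (a * d) / (b * c_)
  p <- phyper(a - 1, length(young_bg), length(bg) - length(young_bg),
              length(sa), lower.tail = FALSE)
  list(odds_ratio = or, p_value = p, table = tab)
}
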