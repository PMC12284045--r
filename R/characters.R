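#' Binary cell-type character matrices
#'
#' A `character_matrix` records, for every cell type (taxon, rows) and every
#' transcription factor (character, columns), whether the factor is part of
#' the type's expressed TF repertoire: 1 = present, 0 = absent, `NA` =
#' missing/unknown. Missing states are treated as the full state set \{0,1\}
#' during parsimony scoring.
#'
#' @param states integer/logical matrix in \{0, 1, NA\} with unique rownames
#'   (taxa) and colnames (characters).
#' @param provenance optional character scalar or per-character vector noting
#'   the source species or namespace.
#' @return An object of class `character_matrix` (an integer matrix with
#'   attributes).
#' @export
character_matrix <- function(states, provenance = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(rownames(states)) || is.null(colnames(states))) {
    stop("`states` must have rownames (taxa) and colnames (characters)")
  }
  if (anyDuplicated(rownames(states))) stop("duplicate taxa")
  if (anyDuplicated(colnames(states))) stop("duplicate characters")
  ok <- is.na(states) | states == 0L | states == 1L
  if (!all(ok)) stop("states must be 0, 1 or NA")
  if (!is.null(provenance) && length(provenance) > 1L &&
      length(provenance) != ncol(states)) {
    stop("`provenance` must be length 1 or one per character")
  }
  structure(states, class = c("character_matrix", class(states)),
            provenance = provenance)
}

#' @method print character_matrix
#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("Character matrix: %d taxa x %d characters (%d missing states)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  m <- unclass(x)
  attr(m, "provenance") <- NULL
  print(m, ...)
  invisible(x)
}

cm_taxa <- function(cm) rownames(cm)

# subsetting keeps class and dimnames
#' @export
`[.character_matrix` <- function(x, i, j, drop = FALSE) {
  out <- unclass(x)[i, j, drop = drop]
  if (is.matrix(out)) {
    structure(out, class = c("character_matrix", class(out)),
              provenance = attr(x, "provenance"))
  } else out
}

#' Binarize transcription-factor presence from cluster profiles
#'
#' A TF is scored present (state 1) in a cell type when it is detected
#' (raw count > 0) in at least `presence_min` of the type's cells — the
#' "expressed in at least 10\% of cells" rule; the boundary is inclusive.
#'
#' @param profile a [cluster_profiles()] object.
#' @param tf_list character vector of TF gene ids.
#' @param presence_min detection-fraction threshold in (0, 1]; default 0.10.
#' @param provenance optional provenance label stored on the result.
#' @return A [character_matrix()] with cell types as taxa and the TFs found
#'   in the profile as characters (original `tf_list` order).
#' @export
binarize_characters <- function(profile, tf_list, presence_min = 0.10,
                                provenance = NULL) {
  stopifnot(inherits(profile, "cluster_profile"))
  if (nrow(profile$frac_expr) < 2L) stop("need at least 2 clusters")
  tf_list <- unique(tf_list)
  tfs <- tf_list[tf_list %in% colnames(profile$frac_expr)]
  if (length(tfs) == 0L) stop("no TF from `tf_list` found in the profile")
  states <- (profile$frac_expr[, tfs, drop = FALSE] >= presence_min) * 1L
  character_matrix(states, provenance = provenance)
}

#' Drop parsimony-uninformative constant characters
#'
#' Keeps only characters that are present in at least one but not in all
#' taxa (over non-missing states); all-0, all-1 and all-missing characters
#' carry no grouping signal and are removed.
#'
#' @param cm a [character_matrix()].
#' @param quiet suppress the per-reason drop report.
#' @return The filtered [character_matrix()].
#' @export
filter_informative <- function(cm, quiet = FALSE) {
  stopifnot(inherits(cm, "character_matrix"))
  if (ncol(cm) == 0L) stop("character matrix has no characters")
  n_one  <- colSums(cm == 1L, na.rm = TRUE)
  n_zero <- colSums(cm == 0L, na.rm = TRUE)
  all_one  <- n_one > 0L & n_zero == 0L
  all_zero <- n_zero > 0L & n_one == 0L
  all_miss <- n_one == 0L & n_zero == 0L
  keep <- !(all_one | all_zero | all_miss)
  if (!quiet) {
    message(sprintf(
      "filter_informative: dropped %d all-present, %d all-absent, %d all-missing; %d kept",
      sum(all_one), sum(all_zero), sum(all_miss), sum(keep)))
  }
  if (!any(keep)) {
    stop("no informative characters remain; consider changing presence_min")
  }
  cm[, keep, drop = FALSE]
}

#' Read an ortholog conversion table
#'
#' @param path TSV with columns `source_gene` and `target_gene` (extra
#'   columns ignored).
#' @param direction optional label, e.g. `"ciona->mouse"`.
#' @return A data.frame of unique (source_gene, target_gene) pairs with a
#'   `direction` attribute.
#' @export
read_ortholog_map <- function(path, direction = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source_gene", "target_gene") %in% names(tab))) {
    stop("ortholog table needs columns source_gene, target_gene")
  }
  tab <- unique(tab[, c("source_gene", "target_gene")])
  attr(tab, "direction") <- direction
  tab
}

#' Re-key a character matrix into an orthologous gene namespace
#'
#' Characters (columns) named by source-species genes are converted to target
#' genes via an ortholog map. When several source genes map to one target,
#' presence combines by OR (`mode = "any"`, a target TF is present if any
#' source paralog is) or AND (`mode = "all"`). Source genes without a target
#' are dropped and counted.
#'
#' @param cm a [character_matrix()] with source-species characters.
#' @param map data.frame with columns `source_gene`, `target_gene`
#'   (see [read_ortholog_map()]).
#' @param mode `"any"` (OR) or `"all"` (AND) for many-to-one combination.
#' @param quiet suppress the conversion report.
#' @return A [character_matrix()] with target-namespace characters.
#' @export
map_orthologs <- function(cm, map, mode = c("any", "all"), quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cm, "character_matrix"))
  if (nrow(map) == 0L) stop("ortholog map is empty")
  map <- map[map$source_gene %in% colnames(cm), , drop = FALSE]
  n_unmapped <- sum(!(colnames(cm) %in% map$source_gene))
  if (nrow(map) == 0L) {
    warning("no character has an ortholog; result is empty")
    out <- unclass(cm)[, 0, drop = FALSE]
    return(character_matrix(out))
  }
  targets <- unique(map$target_gene)
  out <- matrix(NA_integer_, nrow(cm), length(targets),
                dimnames = list(rownames(cm), targets))
  for (tg in targets) {
    src <- map$source_gene[map$target_gene == tg]
    block <- unclass(cm)[, src, drop = FALSE]
    out[, tg] <- if (mode == "any") {
      as.integer(rowSums(block == 1L, na.rm = TRUE) > 0L)
    } else {
      as.integer(rowSums(block == 1L, na.rm = TRUE) == length(src))
    }
    all_na <- rowSums(!is.na(block)) == 0L
    out[all_na, tg] <- NA_integer_
  }
  if (!quiet) {
    message(sprintf("map_orthologs: %d source characters unmapped (dropped), %d targets",
                    n_unmapped, length(targets)))
  }
  character_matrix(out, provenance = attr(cm, "provenance"))
}

#' Join character matrices across species
#'
#' Combines two character matrices that already share a gene namespace
#' (after [map_orthologs()]). Taxa and characters are unioned; a state absent
#' from one source is filled with 0 (`fill = "zero"`, mirroring appending a
#' new taxon column into an existing matrix) or `NA` (`fill = "missing"`,
#' acknowledging that absence of an ortholog is not absence of expression).
#' The informative-character filter is re-applied.
#'
#' @param cm_a,cm_b [character_matrix()] objects.
#' @param fill `"zero"` or `"missing"`.
#' @param quiet suppress the filter report.
#' @return A filtered, joined [character_matrix()].
#' @export
join_character_matrices <- function(cm_a, cm_b, fill = c("zero", "missing"),
                                    quiet = FALSE) {
  fill <- match.arg(fill)
  stopifnot(inherits(cm_a, "character_matrix"), inherits(cm_b, "character_matrix"))
  shared_taxa <- intersect(rownames(cm_a), rownames(cm_b))
  for (tx in shared_taxa) {
    common <- intersect(colnames(cm_a), colnames(cm_b))
    if (!identical(unclass(cm_a)[tx, common], unclass(cm_b)[tx, common])) {
      stop(sprintf("taxon '%s' occurs in both matrices with different states", tx))
    }
  }
  taxa <- union(rownames(cm_a), rownames(cm_b))
  chars <- union(colnames(cm_a), colnames(cm_b))
  fill_val <- if (fill == "zero") 0L else NA_integer_
  out <- matrix(fill_val, length(taxa), length(chars),
                dimnames = list(taxa, chars))
  out[rownames(cm_b), colnames(cm_b)] <- unclass(cm_b)
  out[rownames(cm_a), colnames(cm_a)] <- unclass(cm_a)  # a wins on shared taxa
  filter_informative(character_matrix(out), quiet = quiet)
}

#' Write / read a character matrix as TSV
#'
#' Taxa in rows, characters in columns, states in \{0, 1, ?\} with `?` for
#' missing.
#'
#' @param cm a [character_matrix()].
#' @param path output/input file path.
#' @name character_matrix_io
#' @export
write_character_matrix <- function(cm, path) {
  m <- unclass(cm)
  m[is.na(m)] <- NA
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  for (j in seq_along(df)[-1]) {
    df[[j]] <- ifelse(is.na(df[[j]]), "?", as.character(df[[j]]))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname character_matrix_io
#' @export
read_character_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  taxa <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  states <- matrix(NA_integer_, nrow(m), ncol(m),
                   dimnames = list(taxa, colnames(m)))
  states[m == "0"] <- 0L
  states[m == "1"] <- 1L
  character_matrix(states)
}

#' Export a character matrix in NEXUS format
#'
#' Standard-datatype NEXUS with `?` as the missing symbol, readable by
#' external phylogenetics tools.
#'
#' @param cm a [character_matrix()].
#' @param path output file path.
#' @export
write_nexus <- function(cm, path) {
  m <- unclass(cm)
  sym <- ifelse(is.na(m), "?", as.character(m))
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
    "  MATRIX")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    sprintf("    %s %s", rownames(m)[i], paste(sym[i, ], collapse = ""))
  }, character(1))
  writeLines(c(lines, rows, "  ;", "END;"), path)
  invisible(path)
}
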