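#' Fitch parsimony length of a tree for a binary character matrix
#'
#' Total number of presence/absence changes required on `tree` to explain
#' `cm` under the Fitch small-parsimony criterion: the score of the tree is
#' the sum over characters of the minimum number of state changes, computed
#' by post-order set intersection/union from an arbitrary rooting (the
#' length does not depend on the rooting). Missing leaf states enter as the
#' full state set \{0,1\}.
#'
#' @param tree a `phylo` tree whose tip labels are exactly the taxa of `cm`.
#' @param cm a [character_matrix()] (or 0/1/NA matrix with dimnames).
#' @return Integer parsimony score (total changes).
#' @export
fitch_score <- function(tree, cm) {
  cm <- as_cm(cm)
  if (ncol(cm) < 1L) stop("character matrix has no characters")
  taxa <- rownames(cm)
  if (!setequal(tree$tip.label, taxa) ||
      length(tree$tip.label) != length(taxa)) {
    stop("tree leaves and character-matrix taxa do not match")
  }
  el <- phylo_to_edgelist(tree, taxa)
  cpp_fitch_score(el$edges, cm_codes(cm), el$n_nodes)
}

as_cm <- function(cm) {
  if (inherits(cm, "character_matrix")) return(cm)
  character_matrix(cm)
}

# state-set codes for the C++ core: 1 = {0}, 2 = {1}, 3 = missing = {0,1}
cm_codes <- function(cm) {
  codes <- unclass(cm) + 1L
  codes[is.na(codes)] <- 3L
  attr(codes, "provenance") <- NULL
  codes
}

#' Maximum-parsimony search over cell-type tree topologies
#'
#' Finds the unrooted binary topology (or topologies) over the taxa of `cm`
#' minimizing the total Fitch parsimony length. `"exhaustive"` scores every
#' topology via stepwise leaf insertion; `"branch_and_bound"` prunes partial
#' trees whose score already exceeds the best complete tree found (exact);
#' `"nni"` is a nearest-neighbour-interchange hill climb with random
#' restarts (heuristic, for large taxon sets). `"auto"` chooses exhaustive
#' for up to 9 taxa, branch-and-bound up to 14, NNI beyond.
#'
#' @param cm a [character_matrix()]; at least 3 taxa and 1 informative
#'   character.
#' @param method one of `"auto"`, `"exhaustive"`, `"branch_and_bound"`,
#'   `"nni"`.
#' @param outgroup optional taxon name used to root returned trees for
#'   display; inference itself is unrooted.
#' @param seed integer seed controlling the NNI restarts (exhaustive and
#'   branch-and-bound are deterministic regardless).
#' @param nni_restarts number of random-restart hill climbs for `"nni"`.
#' @return An object of class `mp_search` with elements `best_score`,
#'   `trees` (all co-optimal topologies as `phylo` objects),
#'   `n_topologies_examined`, `method`, `taxa`.
#' @export
search_mp_tree <- function(cm, method = c("auto", "exhaustive",
                                          "branch_and_bound", "nni"),
                           outgroup = NULL, seed = 1L, nni_restarts = 20L) {
  method <- match.arg(method)
  cm <- as_cm(cm)
  n <- nrow(cm)
  if (n < 3L) stop("need at least 3 taxa")
  n_one <- colSums(cm == 1L, na.rm = TRUE)
  n_zero <- colSums(cm == 0L, na.rm = TRUE)
  if (!any(n_one > 0L & n_zero > 0L)) {
    stop("no informative characters: all characters constant")
  }
  if (!is.null(outgroup) && !outgroup %in% rownames(cm)) {
    stop(sprintf("outgroup '%s' is not a taxon", outgroup))
  }
  if (method == "auto") {
    method <- if (n <= 9L) "exhaustive" else if (n <= 14L) "branch_and_bound"
              else "nni"
  }
  taxa <- rownames(cm)
  codes <- cm_codes(cm)

  if (method %in% c("exhaustive", "branch_and_bound")) {
    prune <- method == "branch_and_bound"
    upper <- if (prune) greedy_upper_bound(codes) else -1L
    res <- cpp_mp_search(codes, prune, upper)
    if (res$overflow) {
      warning("more co-optimal trees than stored; list truncated")
    }
    trees <- lapply(res$trees, edgelist_to_phylo, taxa = taxa)
    examined <- res$examined
    best <- res$best_score
  } else {
    nni <- nni_search(codes, n_restarts = nni_restarts, seed = seed)
    trees <- lapply(nni$trees, edgelist_to_phylo, taxa = taxa)
    examined <- nni$examined
    best <- nni$best_score
  }
  if (!is.null(outgroup)) {
    trees <- lapply(trees, function(tr) ape::root(tr, outgroup, resolve.root = TRUE))
  }
  structure(list(best_score = best, trees = trees,
                 n_topologies_examined = examined,
                 method = method, taxa = taxa, outgroup = outgroup),
            class = "mp_search")
}

#' @method print mp_search
#' @export
print.mp_search <- function(x, ...) {
  cat(sprintf("Maximum-parsimony search (%s)\n", x$method))
  cat(sprintf("  taxa: %d; best score: %d changes; co-optimal topologies: %d\n",
              length(x$taxa), x$best_score, length(x$trees)))
  cat(sprintf("  topologies examined: %s\n",
              format(x$n_topologies_examined, big.mark = ",")))
  invisible(x)
}

#' @method summary mp_search
#' @export
summary.mp_search <- function(object, ...) {
  print(object)
  if (length(object$trees) > 1L) {
    cons <- strict_consensus(object$trees)
    cat("Strict consensus of co-optimal trees:\n")
    cat(" ", ape::write.tree(cons), "\n")
  } else {
    cat("Unique optimal topology:\n")
    cat(" ", ape::write.tree(object$trees[[1]]), "\n")
  }
  invisible(object)
}

# greedy stepwise addition followed by one NNI descent: an upper bound used
# to seed the branch-and-bound search
greedy_upper_bound <- function(codes) {
  n <- nrow(codes)
  em <- rbind(c(0L, n), c(1L, n), c(2L, n))
  for (tip in seq_len(max(0L, n - 3L)) + 2L) {
    best_s <- Inf; best_em <- NULL
    new_int <- n + tip - 2L
    for (e in seq_len(nrow(em))) {
      cand <- rbind(em[-e, , drop = FALSE],
                    c(em[e, 1], new_int), c(new_int, em[e, 2]),
                    c(new_int, tip))
      s <- cpp_fitch_score(cand, codes, n + tip - 1L)
      if (s < best_s) { best_s <- s; best_em <- cand }
    }
    em <- best_em
  }
  des <- nni_descent(em, codes)
  des$score
}

# ---- NNI heuristic ---------------------------------------------------------

# one hill-climb from tree `em` to a local optimum
nni_descent <- function(em, codes) {
  n <- nrow(codes)
  n_nodes <- 2L * n - 2L
  s <- cpp_fitch_score(em, codes, n_nodes)
  examined <- 0
  repeat {
    improved <- FALSE
    internal <- which(em[, 1] >= n & em[, 2] >= n)
    for (e in internal) {
      u <- em[e, 1]; v <- em[e, 2]
      eu_idx <- setdiff(which(em[, 1] == u | em[, 2] == u), e)
      ev_idx <- setdiff(which(em[, 1] == v | em[, 2] == v), e)
      x1 <- eu_idx[1]
      for (y in ev_idx) {
        cand <- em
        # swap the subtree attached at x1 (on u's side) with y (on v's side)
        xo <- if (cand[x1, 1] == u) 2L else 1L
        yo <- if (cand[y, 1] == v) 2L else 1L
        xn <- cand[x1, xo]; yn <- cand[y, yo]
        cand[x1, xo] <- yn; cand[y, yo] <- xn
        cand[x1, if (xo == 1L) 2L else 1L] <- u
        cand[y, if (yo == 1L) 2L else 1L] <- v
        s2 <- cpp_fitch_score(cand, codes, n_nodes)
        examined <- examined + 1
        if (s2 < s) { s <- s2; em <- cand; improved <- TRUE; break }
      }
      if (improved) break
    }
    if (!improved) break
  }
  list(edges = em, score = s, examined = examined)
}

random_addition_tree <- function(codes, order_tips) {
  n <- nrow(codes)
  em <- rbind(c(order_tips[1], n), c(order_tips[2], n), c(order_tips[3], n))
  for (k in seq_len(max(0L, n - 3L)) + 3L) {
    tip <- order_tips[k]
    new_int <- n + k - 3L
    best_s <- Inf; best_em <- NULL
    for (e in seq_len(nrow(em))) {
      cand <- rbind(em[-e, , drop = FALSE],
                    c(em[e, 1], new_int), c(new_int, em[e, 2]),
                    c(new_int, tip))
      s <- cpp_fitch_score(cand, codes, n + k - 2L)
      if (s < best_s) { best_s <- s; best_em <- cand }
    }
    em <- best_em
  }
  em
}

nni_search <- function(codes, n_restarts = 20L, seed = 1L) {
  n <- nrow(codes)
  best <- Inf; best_trees <- list(); examined <- 0
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    ord <- if (r == 1L) 0:(n - 1L) else sample(0:(n - 1L))
    em <- random_addition_tree(codes, ord)
    des <- nni_descent(em, codes)
    examined <- examined + des$examined + 1
    if (des$score < best) {
      best <- des$score
      best_trees <- list(des$edges)
    } else if (des$score == best) {
      key <- paste(sort(apply(des$edges, 1, function(z) paste(sort(z), collapse = "-"))),
                   collapse = ";")
      keys <- vapply(best_trees, function(t2) {
        paste(sort(apply(t2, 1, function(z) paste(sort(z), collapse = "-"))),
              collapse = ";")
      }, character(1))
      if (!key %in% keys) best_trees <- c(best_trees, list(des$edges))
    }
  }
  list(best_score = best, trees = best_trees, examined = examined)
}

# ---- consensus, distances, bootstrap ---------------------------------------

#' Strict consensus of trees
#'
#' Keeps exactly the bipartitions shared by every input tree; the result may
#' be non-binary (a star tree when the inputs share nothing).
#'
#' @param trees a list of `phylo` trees (or an `mp_search` object) over the
#'   same leaf set.
#' @return A `phylo` tree.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "mp_search")) trees <- trees$trees
  if (length(trees) < 1L) stop("need at least one tree")
  leaves <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), leaves)) stop("leaf sets differ")
  }
  if (length(trees) == 1L) return(trees[[1]])
  trees <- lapply(trees, ape::unroot)
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1)
}

#' Robinson–Foulds distance between two trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' trees (symmetric difference). Zero iff the unrooted topologies agree.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Integer distance.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label)) {
    stop("leaf sets differ")
  }
  b1 <- bipartition_keys(ape::unroot(t1))
  b2 <- bipartition_keys(ape::unroot(t2))
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Character-resampling bootstrap support
#'
#' Resamples characters (columns) with replacement `B` times, re-runs the
#' parsimony search on each replicate, and annotates each bipartition of the
#' reference optimal tree with the fraction of replicates whose strict
#' consensus of co-optimal trees contains it.
#'
#' @param cm a [character_matrix()].
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed (resampling is deterministic given it).
#' @param method passed to [search_mp_tree()].
#' @return A `phylo` tree (first optimal topology of the full-data search)
#'   with `node.label` support fractions and a `support` attribute keyed by
#'   bipartition.
#' @export
bootstrap_support <- function(cm, B = 100L, seed = 1L, method = "auto") {
  cm <- as_cm(cm)
  if (B < 1L) stop("B must be >= 1")
  full <- search_mp_tree(cm, method = method, seed = seed)
  ref <- full$trees[[1]]
  ref_keys <- bipartition_keys(ref)
  hits <- setNames(numeric(length(ref_keys)), ref_keys)
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample(ncol(cm), replace = TRUE)
    rep_cm <- unclass(cm)[, idx, drop = FALSE]
    colnames(rep_cm) <- sprintf("bs%d", seq_along(idx))
    keep <- colSums(rep_cm == 1L, na.rm = TRUE) > 0L &
            colSums(rep_cm == 0L, na.rm = TRUE) > 0L
    if (!any(keep)) next
    res <- search_mp_tree(character_matrix(rep_cm[, keep, drop = FALSE]),
                          method = method, seed = seed + b)
    cons <- strict_consensus(res$trees)
    bk <- bipartition_keys(cons)
    hits[ref_keys %in% bk] <- hits[ref_keys %in% bk] + 1
  }
  support <- hits / B
  ref <- annotate_support(ref, support)
  attr(ref, "support") <- support
  ref
}

# write support fractions into node labels of the matching internal nodes
annotate_support <- function(tree, support) {
  n <- length(tree$tip.label)
  tree2 <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tree2$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree2$tip.label[i]
  for (e in seq_len(nrow(tree2$edge))) {
    p <- tree2$edge[e, 1]; ch <- tree2$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  anchor <- sort(tree2$tip.label)[1]
  labs <- rep("", tree2$Nnode)
  for (nd in (n + 1):(n + tree2$Nnode)) {
    side <- desc[[nd]]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (anchor %in% side) side <- setdiff(tree2$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      labs[nd - n] <- sprintf("%.2f", support[[key]])
    }
  }
  tree2$node.label <- labs
  tree2
}
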