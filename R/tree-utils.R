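# Conversions between ape "phylo" trees and the 0-based edge-list
# representation used by the C++ search core, plus bipartition utilities.

# tips are numbered 0..n-1 following `taxa`; internal nodes n..(n_nodes-1)
phylo_to_edgelist <- function(tree, taxa) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a 'phylo' object")
  n <- length(tree$tip.label)
  idx <- match(tree$tip.label, taxa)
  if (anyNA(idx) || n != length(taxa)) {
    stop("tree leaves and taxa do not match")
  }
  # ape numbering: tips 1..n, internals n+1..n+Nnode
  remap <- integer(n + tree$Nnode)
  remap[seq_len(n)] <- idx - 1L
  remap[n + seq_len(tree$Nnode)] <- n + seq_len(tree$Nnode) - 1L
  em <- cbind(remap[tree$edge[, 1]], remap[tree$edge[, 2]])
  storage.mode(em) <- "integer"
  list(edges = em, n_nodes = n + tree$Nnode)
}

# Build an ape phylo from a 0-based undirected edge list over `taxa`.
# The tree is returned unrooted (basal multifurcation at an internal node).
edgelist_to_phylo <- function(em, taxa) {
  n <- length(taxa)
  n_nodes <- max(em) + 1L
  n_int <- n_nodes - n
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(em))) {
    a <- em[e, 1] + 1L
    b <- em[e, 2] + 1L
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  root <- if (n_int > 0L) adj[[1L]][1L] else stop("degenerate tree")
  # preorder DFS assigning ape ids: tips keep 1..n, internals n+1, n+2, ...
  new_id <- integer(n_nodes)
  new_id[seq_len(n)] <- seq_len(n)
  next_int <- n
  parent <- integer(n_nodes)
  stack <- root
  seen <- logical(n_nodes)
  seen[root] <- TRUE
  edges <- matrix(0L, nrow = 0L, ncol = 2L)
  order_nodes <- integer(0)
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (nd > n) {
      next_int <- next_int + 1L
      new_id[nd] <- next_int
    }
    order_nodes <- c(order_nodes, nd)
    for (nb in adj[[nd]]) {
      if (!seen[nb]) {
        seen[nb] <- TRUE
        parent[nb] <- nd
        stack <- c(stack, nb)
      }
    }
  }
  for (nd in order_nodes) {
    if (parent[nd] > 0L) {
      edges <- rbind(edges, c(new_id[parent[nd]], new_id[nd]))
    }
  }
  tr <- list(edge = edges, tip.label = taxa, Nnode = n_int)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

# Non-trivial bipartitions of a phylo tree as canonical string keys.
# Each split is represented by the side NOT containing the first taxon
# (sorted label order), so keys are comparable across trees.
bipartition_keys <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4L) return(character(0))
  anchor <- sort(tree$tip.label)[1L]
  tree <- ape::reorder.phylo(tree, "postorder")
  n_nodes <- n + tree$Nnode
  desc <- vector("list", n_nodes)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= n) next                       # trivial: single tip
    side <- desc[[ch]]
    if (length(side) >= n - 1L) next        # trivial: all or all-but-one
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}
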