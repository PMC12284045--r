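# Independent brute-force oracles for the parsimony machinery. These share
# no code with the package's search: topologies are enumerated as newick
# strings by recursive grafting, and character lengths are obtained by
# minimizing over ALL ancestral state assignments.

# all rooted binary topologies (as nested lists) over a taxon set
all_rooted_shapes <- function(taxa) {
  if (length(taxa) == 1L) return(list(taxa[[1]]))
  first <- taxa[[1]]
  rest <- all_rooted_shapes(taxa[-1])
  out <- list()
  for (shape in rest) {
    out <- c(out, graft_everywhere(shape, first))
  }
  out
}

# graft `tip` onto every edge of a rooted shape, plus above the root
graft_everywhere <- function(shape, tip) {
  res <- list(list(shape, tip))
  if (is.list(shape)) {
    for (k in 1:2) {
      for (sub in graft_everywhere(shape[[k]], tip)) {
        mod <- shape
        mod[[k]] <- sub
        res <- c(res, list(mod))
      }
    }
  }
  res
}

shape_to_newick <- function(shape) {
  to_s <- function(s) {
    if (!is.list(s)) return(s)
    paste0("(", to_s(s[[1]]), ",", to_s(s[[2]]), ")")
  }
  paste0(to_s(shape), ";")
}

# every unrooted binary topology over `taxa`, as ape phylo objects:
# unrooted trees on n taxa == rooted trees on taxa[-1] with taxa[1] joined
# at the root (then unrooted)
oracle_all_topologies <- function(taxa) {
  shapes <- all_rooted_shapes(as.list(taxa[-1]))
  lapply(shapes, function(s) {
    ape::unroot(ape::read.tree(text = shape_to_newick(list(s, taxa[1]))))
  })
}

# minimum changes for the whole matrix on one tree, by enumerating all
# 2^Nnode internal state assignments (NA leaves enumerated too)
oracle_tree_length <- function(tree, states) {
  n <- length(tree$tip.label)
  n_int <- tree$Nnode
  edge <- tree$edge
  leaf_states <- states[tree$tip.label, , drop = FALSE]
  n_char <- ncol(states)
  na_leaves <- which(rowSums(is.na(leaf_states)) > 0)
  stopifnot(length(na_leaves) == 0L)  # oracle used on complete matrices
  best <- rep(Inf, n_char)
  for (code in 0:(2^n_int - 1L)) {
    a <- as.integer(intToBits(code)[seq_len(n_int)])
    node_states <- rbind(leaf_states, matrix(a, n_int, n_char))
    cost <- colSums(abs(node_states[edge[, 1], , drop = FALSE] -
                        node_states[edge[, 2], , drop = FALSE]))
    best <- pmin(best, cost)
  }
  sum(best)
}

# per-character oracle allowing NA leaves (free nodes enumerated)
oracle_char_length <- function(tree, char_states) {
  n <- length(tree$tip.label)
  n_int <- tree$Nnode
  edge <- tree$edge
  s <- char_states[tree$tip.label]
  free <- c(which(is.na(s)), n + seq_len(n_int))
  best <- Inf
  for (code in 0:(2^length(free) - 1L)) {
    a <- as.integer(intToBits(code)[seq_along(free)])
    ns <- c(s, rep(NA_integer_, n_int))
    ns[free] <- a
    best <- min(best, sum(abs(ns[edge[, 1]] - ns[edge[, 2]])))
  }
  best
}

# global optimum over all topologies (score + optimal newick strings)
oracle_best_score <- function(states) {
  taxa <- rownames(states)
  topos <- oracle_all_topologies(taxa)
  scores <- vapply(topos, oracle_tree_length, numeric(1), states = states)
  list(best = min(scores),
       n_topologies = length(topos),
       optimal = topos[scores == min(scores)])
}

# random binary matrix guaranteed to keep >= 1 informative character
random_cm <- function(n_taxa, n_char, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_taxa * n_char, 1, 0.5), n_taxa, n_char,
                dimnames = list(paste0("t", seq_len(n_taxa)),
                                paste0("c", seq_len(n_char))))
    ones <- colSums(m)
    if (any(ones > 0 & ones < n_taxa)) return(character_matrix(m))
  }
}

# tiny normalized dataset used across preprocessing/marker tests
toy_counts <- function(mat, clusters) {
  dimnames(mat) <- list(paste0("cell", seq_len(nrow(mat))),
                        paste0("g", seq_len(ncol(mat))))
  cell_counts(mat, cluster = clusters)
}
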