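# Shared fixtures built in code.

# Small rooted trees used across tests (branch lengths in dS units).
two_leaf_tree <- function(a = 0.01, b = 0.02) {
  parse_newick(sprintf("(A:%g,B:%g);", a, b))
}

balanced4_tree <- function() {
  parse_newick("((A:0.02,B:0.03):0.01,(C:0.015,D:0.025):0.012);")
}

caterpillar5_tree <- function() {
  parse_newick(
    "((((A:0.02,B:0.03):0.01,C:0.025):0.012,D:0.03):0.008,E:0.04);")
}

# Random codon assignment for the leaves of a tree (sense codons only).
random_leaf_codons <- function(tree, seed) {
  set.seed(seed)
  tb <- codon_tables()
  codons <- sample(tb$codons, length(tree$tip.label), replace = TRUE)
  names(codons) <- tree$tip.label
  codons
}

# Brute-force enumeration oracle for one codon site: explicit sum over all
# joint assignments of internal-node states (61^k terms, one edge-product
# per term). Independent of the pruning recursion. Returns the site
# likelihood and, if `node` is given, that node's marginal posterior.
# Feasible up to 4 internal nodes (5-leaf rooted binary trees).
brute_force_site <- function(tree, leaf_codons, model, node = NULL) {
  tb <- codon_tables()
  n <- length(tb$codons)
  et <- edge_table(tree)
  P <- lapply(et$length, function(t) transition_matrix(model, t))
  n_tip <- length(tree$tip.label)
  internals <- sort(unique(et$parent))
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  leaf_state <- unname(codon_tables()$codon_index[leaf_codons[tree$tip.label]])
  others <- setdiff(internals, root)
  stopifnot(length(others) <= 3)

  grid <- if (length(others)) {
    as.matrix(do.call(expand.grid, rep(list(seq_len(n)), length(others))))
  } else {
    matrix(0L, 1, 0)
  }
  ch_col <- function(v) {
    if (v <= n_tip) rep(leaf_state[v], nrow(grid)) else grid[, match(v, others)]
  }
  # product over all edges not incident to the root (independent of r)
  base <- rep(1, nrow(grid))
  root_edges <- integer(0)
  for (e in seq_len(nrow(et))) {
    if (et$parent[e] == root) {
      root_edges <- c(root_edges, e)
    } else {
      base <- base * P[[e]][cbind(ch_col(et$parent[e]), ch_col(et$child[e]))]
    }
  }
  lik <- 0
  post <- numeric(n)
  for (r in seq_len(n)) {
    term <- model$freqs[r] * base
    for (e in root_edges) {
      term <- term * P[[e]][cbind(rep(r, nrow(grid)), ch_col(et$child[e]))]
    }
    tot_r <- sum(term)
    lik <- lik + tot_r
    if (!is.null(node)) {
      if (node == root) {
        post[r] <- post[r] + tot_r
      } else {
        post <- post + rowsum(term, grid[, match(node, others)])[, 1]
      }
    }
  }
  list(likelihood = unname(lik),
       posterior = if (!is.null(node)) unname(post / sum(post)))
}
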