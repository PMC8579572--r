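# Tree builders and independent brute-force oracles used across the suite.
# The oracles work directly on the edge matrix and never call the package's
# traversal code.

caterpillar_newick <- function(n) {
  s <- paste0("(t1,t2)")
  for (i in seq_len(n - 2L) + 2L) s <- paste0("(", s, ",t", i, ")")
  paste0(s, ";")
}

caterpillar_tree <- function(n) read_newick(text = caterpillar_newick(n))[[1]]

balanced_newick <- function(n) {
  stopifnot(log2(n) %% 1 == 0)
  labs <- paste0("t", seq_len(n))
  while (length(labs) > 1L) {
    labs <- vapply(seq_len(length(labs) / 2L), function(i)
      paste0("(", labs[2L * i - 1L], ",", labs[2L * i], ")"), character(1))
  }
  paste0(labs, ";")
}

balanced_tree <- function(n) read_newick(text = balanced_newick(n))[[1]]

# random binary topology through ape (independent of the simulator)
random_tree <- function(n) ape::rtree(n)

# --- oracles ---------------------------------------------------------------

# ancestors of a node (self excluded, root included), straight off the edges
oracle_ancestors <- function(phy, v) {
  par <- integer(max(phy$edge))
  par[phy$edge[, 2]] <- phy$edge[, 1]
  out <- integer(0)
  while (par[v] != 0L) {
    v <- par[v]
    out <- c(out, v)
  }
  out
}

oracle_depth <- function(phy, v) length(oracle_ancestors(phy, v))

# total cophenetic index by explicit LCA over all tip pairs
oracle_cophenetic <- function(phy) {
  n <- length(phy$tip.label)
  tot <- 0L
  for (i in seq_len(n - 1L)) {
    ai <- c(i, oracle_ancestors(phy, i))
    for (j in (i + 1L):n) {
      aj <- c(j, oracle_ancestors(phy, j))
      lca <- intersect(ai, aj)[1L]  # both lists are leaf-to-root ordered
      tot <- tot + oracle_depth(phy, lca)
    }
  }
  tot
}

oracle_sackin <- function(phy) {
  n <- length(phy$tip.label)
  sum(vapply(seq_len(n), function(v) oracle_depth(phy, v), integer(1)))
}

# sup distance between the two empirical CDFs, scanned over all data points
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

# AUC as the positive-negative concordance probability (ties count 1/2)
oracle_auc <- function(truth, scores) {
  pos <- scores[truth == "structured"]
  neg <- scores[truth != "structured"]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# exact permutation p-value by enumerating all choose(N, n1) splits
oracle_exact_perm_p <- function(x, y, stat_fun) {
  z <- c(x, y)
  n1 <- length(x)
  obs <- stat_fun(z[seq_len(n1)], z[-seq_len(n1)])
  splits <- utils::combn(length(z), n1)
  vals <- apply(splits, 2, function(idx) stat_fun(z[idx], z[-idx]))
  mean(vals >= obs - 1e-12)
}

# mirrored copy of a tree (children visited in reverse order)
mirror_tree <- function(phy) {
  ch <- phylostruct:::children_list(phy)
  root <- phylostruct:::tree_root(phy)
  edge <- matrix(0L, nrow(phy$edge), 2L)
  k <- 0L
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- ch[[v]]
    for (c in kids) {          # no rev(): reverses DFS child order
      k <- k + 1L
      edge[k, ] <- c(v, c)
      stack <- c(stack, c)
    }
  }
  out <- phy
  out$edge <- edge
  if (!is.null(phy$edge.length)) {
    len <- numeric(max(phy$edge))
    len[phy$edge[, 2]] <- phy$edge.length
    out$edge.length <- len[edge[, 2]]
  }
  out
}

# standard structured/unstructured parameter sets used in several tests
hiv_deme1 <- function() deme_params(birth_rate_for_r0(4.99, 0.014, 0.3),
                                    0.014, 0.3)
hiv_deme2 <- function() deme_params(birth_rate_for_r0(9.09, 0.042, 0.2),
                                    0.042, 0.2)
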