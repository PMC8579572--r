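# Topological tree-shape statistics.
#
# All statistics are purely topological (branch lengths never enter).
# Conventions for unifurcating migration (deme-change) nodes:
#   * depth-type statistics (Sackin, maximum depth, maximum width, the LCA
#     depths of the total cophenetic index) count migration nodes and their
#     edges;
#   * balance-type statistics (cherries, Colless) treat migration nodes as
#     transparent pass-throughs: they have a single child, so they
#     contribute no imbalance term and simply pass subtended-leaf counts
#     through;
#   * ladder length counts internal nodes with exactly one leaf child, so a
#     migration node counts only when its single child is a leaf.
# These conventions jointly reproduce the worked example shipped as
# example_structured_tree().

#' Number of cherries
#'
#' A cherry is an internal node whose children are exactly two leaves.
#'
#' @param phy a rooted `phylo` object (unifurcating migration nodes
#'   allowed).
#' @return integer cherry count.
#' @export
count_cherries <- function(phy) {
  if (n_tips(phy) < 2L) stop("need at least 2 tips")
  n <- n_tips(phy)
  ch <- children_list(phy)
  sum(vapply(ch[-seq_len(n)],
             function(k) length(k) == 2L && all(k <= n), logical(1)))
}

#' Sackin index
#'
#' Sum over leaves of the number of edges from the leaf to the root;
#' migration edges are counted.
#'
#' @inheritParams count_cherries
#' @return integer Sackin index.
#' @export
sackin_index <- function(phy) {
  d <- node_depths(phy)
  sum(d[seq_len(n_tips(phy))])
}

#' Colless index
#'
#' Sum over bifurcating internal nodes of the absolute difference between
#' the numbers of leaves subtended by the two children. Migration
#' unifurcations contribute nothing and pass leaf counts through; a node
#' with more than two children is an error.
#'
#' @inheritParams count_cherries
#' @return integer Colless index.
#' @export
colless_index <- function(phy) {
  n <- n_tips(phy)
  ch <- children_list(phy)
  sizes <- vapply(ch[-seq_len(n)], length, integer(1))
  if (any(sizes > 2L)) stop("non-binary tree: a node has > 2 children")
  tu <- tips_under(phy)
  tot <- 0L
  for (v in which(sizes == 2L) + n) {
    k <- ch[[v]]
    tot <- tot + abs(tu[k[1]] - tu[k[2]])
  }
  tot
}

#' Total cophenetic index
#'
#' Sum over all unordered leaf pairs of the edge-depth of their lowest
#' common ancestor (root depth 0); migration edges count towards depth.
#' Computed through the identity that a pair's LCA depth equals the number
#' of its non-root common ancestors, i.e. the index is the sum of
#' `choose(leaves_under(v), 2)` over all non-root nodes `v`.
#'
#' @inheritParams count_cherries
#' @return integer total cophenetic index.
#' @export
total_cophenetic <- function(phy) {
  tu <- tips_under(phy)
  root <- tree_root(phy)
  sum(choose(tu[-root], 2L))
}

#' Ladder length
#'
#' Longest chain of connected internal nodes each having exactly one leaf
#' child, divided by the number of leaves.
#'
#' @inheritParams count_cherries
#' @return ladder length in `[0, 1)`.
#' @export
ladder_length <- function(phy) {
  n <- n_tips(phy)
  ch <- children_list(phy)
  ntot <- n + phy$Nnode
  flagged <- logical(ntot)
  for (v in (n + 1L):ntot)
    flagged[v] <- sum(ch[[v]] <= n) == 1L
  best <- 0L
  chain <- integer(ntot)
  # children precede parents in reverse preorder
  for (v in rev(preorder_nodes(phy))) {
    if (v <= n || !flagged[v]) next
    below <- ch[[v]][ch[[v]] > n]
    ext <- if (length(below)) max(chain[below]) else 0L
    chain[v] <- 1L + ext
    if (chain[v] > best) best <- chain[v]
  }
  best / n
}

#' Maximum depth
#'
#' Largest number of edges from the root to a leaf; migration edges count.
#'
#' @inheritParams count_cherries
#' @return integer maximum depth.
#' @export
max_tree_depth <- function(phy) {
  d <- node_depths(phy)
  max(d[seq_len(n_tips(phy))])
}

#' Maximum width
#'
#' Largest number of nodes (tips, bifurcations and migration nodes alike)
#' found at any single edge-depth.
#'
#' @inheritParams count_cherries
#' @return integer maximum width.
#' @export
max_tree_width <- function(phy) {
  d <- node_depths(phy)
  max(tabulate(d + 1L))
}

#' Width-to-depth ratio
#'
#' @inheritParams count_cherries
#' @return `max_tree_width(phy) / max_tree_depth(phy)`.
#' @export
width_depth_ratio <- function(phy) {
  if (n_tips(phy) < 2L) stop("zero depth: single-tip tree")
  max_tree_width(phy) / max_tree_depth(phy)
}

#' Normalise raw shape statistics
#'
#' Cherries are divided by `n/2`, Sackin by `0.5*n*(n+1) - 1`, Colless by
#' `(n-1)*(n-2)/2`, where `n` is the number of tips.
#'
#' @param cherries,sackin,colless raw statistic values.
#' @param n_tips number of tips (`n >= 3` for the Colless normalisation).
#' @return named list `cherries_norm`, `sackin_norm`, `colless_norm`.
#' @export
normalise_stats <- function(cherries, sackin, colless, n_tips) {
  if (n_tips < 3L) stop("Colless normalisation requires n >= 3")
  list(cherries_norm = cherries / (n_tips / 2),
       sackin_norm = sackin / (0.5 * n_tips * (n_tips + 1) - 1),
       colless_norm = colless / ((n_tips - 1) * (n_tips - 2) / 2))
}

#' All tree-shape statistics of one tree
#'
#' Computes the eight raw statistics and the three normalisations as a
#' single named list; `width_depth_ratio` is recomputed from the returned
#' width and depth.
#'
#' @inheritParams count_cherries
#' @return a named list with components `n_tips`, `cherries`, `sackin`,
#'   `colless`, `total_cophenetic`, `ladder_length`, `max_depth`,
#'   `max_width`, `width_depth_ratio`, `cherries_norm`, `sackin_norm`,
#'   `colless_norm`.
#' @export
tree_shape_stats <- function(phy) {
  validate_tree(phy)
  n <- n_tips(phy)
  cher <- count_cherries(phy)
  sack <- sackin_index(phy)
  coll <- colless_index(phy)
  md <- max_tree_depth(phy)
  mw <- max_tree_width(phy)
  norm <- normalise_stats(cher, sack, coll, n)
  c(list(n_tips = n, cherries = cher, sackin = sack, colless = coll,
         total_cophenetic = total_cophenetic(phy),
         ladder_length = ladder_length(phy),
         max_depth = md, max_width = mw,
         width_depth_ratio = mw / md),
    norm)
}

#' Shape-statistic table for a set of trees
#'
#' @param trees a list of `phylo` objects (e.g. a `multiPhylo`).
#' @param labels optional per-tree labels (e.g. `"structured"` /
#'   `"non-structured"`).
#' @param tree_id optional tree identifiers; defaults to `tree1, tree2, ...`.
#' @return a data frame with one row per tree: `tree_id`, `label`,
#'   `n_tips` and the eleven statistic columns.
#' @export
tree_stats_table <- function(trees, labels = NULL, tree_id = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  m <- length(trees)
  if (is.null(tree_id)) tree_id <- paste0("tree", seq_len(m))
  if (anyDuplicated(tree_id)) stop("duplicate tree ids")
  if (is.null(labels)) labels <- rep(NA_character_, m)
  rows <- lapply(trees, function(tr) as.data.frame(tree_shape_stats(tr)))
  out <- do.call(rbind, rows)
  cbind(data.frame(tree_id = tree_id, label = as.character(labels),
                   stringsAsFactors = FALSE), out)
}

#' The five-tip worked-example tree
#'
#' A pinned five-tip structured phylogeny with internal nodes labelled A-E
#' and one migration (deme-change) node B, used throughout the
#' documentation and tests as the reference for the migration-node
#' statistic conventions. Its statistics are: 2 cherries (0.8 normalised),
#' Sackin 14 (1 normalised), Colless 2 (0.3333 normalised), total
#' cophenetic 6, ladder length 0.2, maximum depth 3, maximum width 4,
#' width-depth ratio 4/3.
#'
#' @return a `phylo` object with a `deme` vector and node labels.
#' @export
example_structured_tree <- function() {
  txt <- paste0("(((1[&deme=2]:1,2[&deme=2]:1)E[&deme=2]:1)B[&deme=1]:1,",
                "(3[&deme=1]:1,(4[&deme=1]:1,5[&deme=1]:1)D[&deme=1]:1)",
                "C[&deme=1]:1)A[&deme=1];")
  read_newick(text = txt)[[1]]
}
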