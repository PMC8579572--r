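# Internal tree machinery.
#
# Trees are "phylo" objects in the ape numbering convention (tips 1..n,
# internal nodes n+1..n+Nnode, root = n+1), except that unifurcating internal
# nodes are allowed: a migration (deme-change) event is represented by an
# internal node with a single child whose deme label differs from its own.
# A per-node integer vector `deme` (length n + Nnode) travels with the tree
# when demes are known; trees of unknown provenance simply lack it.

#' Construct a (possibly unifurcating) rooted phylogeny
#'
#' Builds a rooted `phylo` object from an edge matrix, allowing internal
#' nodes with a single child (used to represent migration events between
#' demes). Input node ids must follow the ape convention.
#'
#' @param edge two-column integer matrix of parent, child node ids.
#' @param tip.label character vector of tip labels (tips are ids `1..n`).
#' @param edge.length optional numeric vector of branch lengths, one per edge.
#' @param deme optional integer vector of deme labels (1 or 2), one per node
#'   in id order (tips first, then internal nodes).
#' @param node.label optional character vector of internal node labels.
#' @return an object of class `phylo`, with a `deme` component when supplied.
#' @export
structured_phylo <- function(edge, tip.label, edge.length = NULL,
                             deme = NULL, node.label = NULL) {
  storage.mode(edge) <- "integer"
  n <- length(tip.label)
  nnode <- length(unique(edge[, 1L]))
  phy <- list(edge = edge, tip.label = tip.label, Nnode = nnode)
  if (!is.null(edge.length)) phy$edge.length <- as.numeric(edge.length)
  if (!is.null(node.label)) phy$node.label <- node.label
  if (!is.null(deme)) phy$deme <- as.integer(deme)
  class(phy) <- "phylo"
  validate_tree(phy)
  phy
}

# Basic structural checks; stops with an informative error.
validate_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object")
  edge <- phy$edge
  n <- length(phy$tip.label)
  ids <- seq_len(n + phy$Nnode)
  if (any(!(edge %in% ids))) stop("edge matrix refers to unknown node ids")
  kids <- tabulate(edge[, 2L], nbins = n + phy$Nnode)
  if (any(kids > 1L)) stop("a node has more than one parent")
  roots <- setdiff(unique(edge[, 1L]), edge[, 2L])
  if (length(roots) != 1L) stop("tree must have exactly one root")
  if (!is.null(phy$deme) && length(phy$deme) != n + phy$Nnode)
    stop("'deme' must have one entry per node")
  invisible(phy)
}

n_tips <- function(phy) length(phy$tip.label)

tree_root <- function(phy) {
  # ape convention puts the root at n+1, but be tolerant of parsed trees
  cand <- setdiff(unique(phy$edge[, 1L]), phy$edge[, 2L])
  cand[1L]
}

# children list indexed by node id (integer(0) for tips)
children_list <- function(phy) {
  ntot <- n_tips(phy) + phy$Nnode
  ch <- vector("list", ntot)
  for (i in seq_len(ntot)) ch[[i]] <- integer(0)
  sp <- split(phy$edge[, 2L], phy$edge[, 1L])
  ch[as.integer(names(sp))] <- sp
  ch
}

# parent vector indexed by node id (0 for the root)
parent_vec <- function(phy) {
  ntot <- n_tips(phy) + phy$Nnode
  par <- integer(ntot)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par
}

# nodes in preorder (root first); every parent precedes its children
preorder_nodes <- function(phy) {
  ch <- children_list(phy)
  ntot <- n_tips(phy) + phy$Nnode
  out <- integer(ntot)
  stack <- tree_root(phy)
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- v
    kids <- ch[[v]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  out[seq_len(k)]
}

# edge-count depth of every node (root = 0); migration edges count
node_depths <- function(phy) {
  par <- parent_vec(phy)
  d <- integer(length(par))
  for (v in preorder_nodes(phy)) {
    d[v] <- if (par[v] == 0L) 0L else d[par[v]] + 1L
  }
  d
}

# number of descendant tips under each node (tips themselves = 1)
tips_under <- function(phy) {
  par <- parent_vec(phy)
  n <- n_tips(phy)
  cnt <- integer(length(par))
  cnt[seq_len(n)] <- 1L
  for (v in rev(preorder_nodes(phy))) {
    if (par[v] != 0L) cnt[par[v]] <- cnt[par[v]] + cnt[v]
  }
  cnt
}

is_tip <- function(phy, v) v <= n_tips(phy)
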