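# Newick reading/writing.
#
# ape's read.tree/write.tree are the natural tools for plain binary trees,
# but the simulator's output dialect needs two things ape discards:
# unifurcating migration nodes must survive serialisation, and per-node deme
# labels are carried in bracketed comments ([&deme=1]). A small tokenising
# parser therefore handles the dialect here; plain Newick (no comments, no
# unifurcations) round-trips identically through ape, which the test suite
# uses as a cross-check.

#' Read rooted trees from a Newick file or string
#'
#' Parses one tree per `;`-terminated statement. Unifurcating (single-child)
#' internal nodes are preserved, and node comments of the form `[&deme=k]`
#' (or a bare integer comment `[k]`) are captured into the tree's `deme`
#' vector.
#'
#' @param file path to a Newick file, or `NULL` when `text` is given.
#' @param text optional character vector of Newick strings.
#' @return a list of `phylo` objects (class `multiPhylo`).
#' @export
#' @examples
#' tr <- read_newick(text = "((a,b),c);")[[1]]
read_newick <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(file)) stop("file not found: ", file)
    text <- readLines(file, warn = FALSE)
  }
  src <- paste(text, collapse = "")
  stmts <- strsplit(src, ";", fixed = TRUE)[[1]]
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]
  if (!length(stmts)) stop("no Newick statements found")
  out <- lapply(seq_along(stmts), function(i) {
    tryCatch(parse_newick_one(stmts[[i]]),
             error = function(e) stop("Newick parse error in tree ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  class(out) <- "multiPhylo"
  out
}

# --- internal parser -------------------------------------------------------

newick_tokens <- function(s) {
  pat <- "\\(|\\)|,|\\[[^]\\[]*\\]|:[-+0-9.eE]+|[^(),:;\\[\\]\\s]+"
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1) stop("empty statement")
  regmatches(s, list(m))[[1]]
}

parse_newick_one <- function(s) {
  toks <- newick_tokens(s)
  ntok <- length(toks)
  # growing node store; parents resolved on the way out of each clause
  lab <- character(0); len <- numeric(0); dem <- integer(0)
  par <- integer(0); isleaf <- logical(0)
  nn <- 0L
  new_node <- function(leaf) {
    nn <<- nn + 1L
    lab[nn] <<- ""; len[nn] <<- NA_real_; dem[nn] <<- NA_integer_
    par[nn] <<- 0L; isleaf[nn] <<- leaf
    nn
  }
  parse_comment <- function(txt) {
    body <- sub("^\\[", "", sub("\\]$", "", txt))
    m <- regmatches(body, regexec("deme=([0-9]+)", body))[[1]]
    if (length(m) == 2L) return(as.integer(m[2]))
    if (grepl("^[0-9]+$", body)) return(as.integer(body))
    NA_integer_
  }
  pos <- 1L
  peek <- function() if (pos <= ntok) toks[pos] else ""
  advance <- function() { pos <<- pos + 1L }

  parse_clade <- function() {
    tk <- peek()
    if (tk == "(") {
      advance()
      kids <- integer(0)
      repeat {
        kids <- c(kids, parse_clade())
        tk <- peek()
        if (tk == ",") { advance(); next }
        if (tk == ")") { advance(); break }
        stop("expected ',' or ')' near token ", pos)
      }
      v <- new_node(FALSE)
      par[kids] <<- v
    } else {
      if (tk %in% c(")", ",", "") || startsWith(tk, ":") || startsWith(tk, "["))
        stop("expected a leaf label near token ", pos)
      v <- new_node(TRUE)
      lab[v] <<- tk
      advance()
    }
    # optional: label (internal), comment, branch length in any sane order
    repeat {
      tk <- peek()
      if (startsWith(tk, "[")) { dem[v] <<- parse_comment(tk); advance() }
      else if (startsWith(tk, ":")) { len[v] <<- as.numeric(substring(tk, 2)); advance() }
      else if (!isleaf[v] && lab[v] == "" &&
               !(tk %in% c("(", ")", ",", ""))) { lab[v] <<- tk; advance() }
      else break
    }
    v
  }
  root <- parse_clade()
  if (pos <= ntok) stop("trailing tokens after tree")

  # renumber to ape convention: tips 1..n in parse order, root = n+1,
  # remaining internal nodes in preorder
  tips <- which(isleaf)
  internals <- which(!isleaf)
  n <- length(tips)
  if (n < 1L) stop("tree has no tips")
  newid <- integer(nn)
  newid[tips] <- seq_len(n)
  # preorder over internals starting at root
  kidlist <- split(seq_len(nn), factor(par, levels = 0:nn))
  ord <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (!isleaf[v]) {
      ord <- c(ord, v)
      stack <- c(stack, rev(kidlist[[as.character(v)]]))
    }
  }
  newid[ord] <- n + seq_along(ord)
  edge <- cbind(newid[par[par > 0L]], newid[which(par > 0L)])
  # reorder edges so parents precede children (preorder rank of the child)
  pre <- integer(nn)
  rank <- 1L
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    pre[v] <- rank; rank <- rank + 1L
    if (!isleaf[v]) stack <- c(stack, rev(kidlist[[as.character(v)]]))
  }
  child_old <- which(par > 0L)
  eord <- order(pre[child_old])
  edge <- edge[eord, , drop = FALSE]

  tip.label <- lab[tips]
  node.label <- lab[ord]
  edge.length <- len[child_old][eord]
  deme <- integer(n + length(ord))
  deme[newid[c(tips, ord)]] <- dem[c(tips, ord)]
  phy <- list(edge = edge, tip.label = tip.label, Nnode = length(ord))
  if (any(!is.na(edge.length))) {
    edge.length[is.na(edge.length)] <- 0
    phy$edge.length <- edge.length
  }
  if (any(nzchar(node.label))) phy$node.label <- node.label
  if (any(!is.na(deme))) phy$deme <- deme
  class(phy) <- "phylo"
  validate_tree(phy)
  phy
}

#' Write trees to Newick, preserving migration nodes and deme labels
#'
#' Serialises each tree on one line. Unifurcating migration nodes are written
#' as single-child clauses; when the tree carries a `deme` vector the labels
#' are emitted as `[&deme=k]` node comments.
#'
#' @param trees a `phylo` object or list of them.
#' @param file optional output path; when `NULL` the strings are returned.
#' @param deme_comments write `[&deme=k]` comments when demes are present.
#' @param digits significant digits for branch lengths.
#' @return invisibly (or visibly when `file` is `NULL`), a character vector.
#' @export
write_newick <- function(trees, file = NULL, deme_comments = TRUE, digits = 10) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  out <- vapply(trees, deparse_newick_one, character(1),
                deme_comments = deme_comments, digits = digits)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

deparse_newick_one <- function(phy, deme_comments = TRUE, digits = 10) {
  ch <- children_list(phy)
  n <- n_tips(phy)
  has_len <- !is.null(phy$edge.length)
  lenof <- numeric(n + phy$Nnode)
  if (has_len) lenof[phy$edge[, 2L]] <- phy$edge.length
  nlab <- phy$node.label
  deme <- if (deme_comments) phy$deme else NULL
  root <- tree_root(phy)
  suffix <- function(v) {
    s <- ""
    if (v > n && !is.null(nlab)) s <- paste0(s, nlab[v - n])
    if (!is.null(deme) && !is.na(deme[v]))
      s <- paste0(s, "[&deme=", deme[v], "]")
    if (has_len && v != root)
      s <- paste0(s, ":", format(lenof[v], digits = digits))
    s
  }
  build <- function(v) {
    if (v <= n) return(paste0(phy$tip.label[v], suffix(v)))
    inner <- paste(vapply(ch[[v]], build, character(1)), collapse = ",")
    paste0("(", inner, ")", suffix(v))
  }
  paste0(build(root), ";")
}
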