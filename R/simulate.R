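# Stochastic birth-death-migration tree simulation.
#
# The process runs in continuous time over one or two demes. With N_i(t)
# extant lineages in deme i and per-lineage rates (birth, death, emigration)
# = (l_i, m_i, a_ij), the waiting time to the next event in deme i is
# exponential with rate N_i(t) * T_i where T_i = l_i + m_i + a_ij. The deme
# of the next event is chosen by comparing a uniform draw with
# T_i / (T_i + T_j) (sub-total-rate weighting; a population-weighted
# alternative using N_i * T_i is available), the event type within the deme
# by comparing a second uniform draw with the cumulative rate fractions
# l_i/T_i (birth) and (l_i + a_ij)/T_i (migration), death otherwise. The
# lineage experiencing the event is uniform among the deme's extant
# lineages. Simulation stops once the configured number of extant lineages
# is reached; dead lineages are pruned and the crown tree (rooted at the
# first bifurcation with surviving descendants on both sides) is returned,
# with migration events kept as unifurcating deme-change nodes.

# event type codes in the raw node store
.BIF <- 1L; .MIG <- 2L; .DEAD <- 3L; .TIP <- 4L

#' Waiting time to the next event in a deme
#'
#' Draws an exponential waiting time with rate `n_lineages * (birth + death
#' + migration)`.
#'
#' @param n_lineages number of extant lineages in the deme.
#' @param params a [deme_params()] object.
#' @return a positive waiting time, in model time units.
#' @export
waiting_time <- function(n_lineages, params) {
  rate <- n_lineages * (params$birth + params$death + params$migration)
  if (!is.finite(rate) || rate <= 0)
    stop("deme inactive: total event rate is zero")
  rexp(1L, rate)
}

#' Select the deme of the next event
#'
#' The default rule weights demes by their per-lineage sub-total rates
#' `T_i = birth + death + migration` only: deme 1 is chosen when
#' `u <= T_1 / (T_1 + T_2)`. The `"population"` option weights by
#' `N_i * T_i` instead (the standard Gillespie deme choice). Demes with no
#' extant lineages receive zero weight under either rule.
#'
#' @param counts integer vector `(N1, N2)` of extant lineages per deme.
#' @param deme1,deme2 [deme_params()] for each deme.
#' @param u uniform draw in `[0, 1]`; defaults to a fresh draw.
#' @param weighting `"subtotal"` (default) or `"population"`.
#' @return the selected deme index, 1 or 2.
#' @export
select_deme <- function(counts, deme1, deme2, u = runif(1L),
                        weighting = c("subtotal", "population")) {
  weighting <- match.arg(weighting)
  if (sum(counts) == 0L) stop("population extinct: no extant lineages")
  t1 <- deme1$birth + deme1$death + deme1$migration
  t2 <- deme2$birth + deme2$death + deme2$migration
  w1 <- if (counts[1] > 0L) t1 else 0
  w2 <- if (counts[2] > 0L) t2 else 0
  if (weighting == "population") {
    w1 <- counts[1] * t1
    w2 <- counts[2] * t2
  }
  if (u <= w1 / (w1 + w2)) 1L else 2L
}

#' Select the event type within a deme
#'
#' Birth when `sigma <= birth/T`, migration when `birth/T < sigma <=
#' (birth + migration)/T`, death otherwise, where `T` is the deme sub-total
#' rate.
#'
#' @param params a [deme_params()] object.
#' @param sigma uniform draw in `[0, 1]`; defaults to a fresh draw.
#' @return one of `"birth"`, `"migration"`, `"death"`.
#' @export
select_event <- function(params, sigma = runif(1L)) {
  if (sigma < 0 || sigma > 1) stop("invalid draw: sigma outside [0, 1]")
  tot <- params$birth + params$death + params$migration
  if (tot <= 0) stop("deme inactive: total event rate is zero")
  s <- sigma * tot
  if (s <= params$birth) "birth"
  else if (s <= params$birth + params$migration) "migration"
  else "death"
}

# --- core event loop -------------------------------------------------------

# Runs one attempt; returns raw node arrays or NULL on extinction.
# Rates are passed as length-2 vectors (lam, mu, alf); targets as in the
# stop rule. All RNG comes from the current global stream.
sim_attempt <- function(lam, mu, alf, start_deme, targets, stop_rule,
                        weighting, max_events) {
  Ts <- lam + mu + alf
  cap <- 4096L
  par <- integer(cap); tim <- numeric(cap); dem <- integer(cap)
  typ <- integer(cap)
  nn <- 0L
  ex <- list(integer(512L), integer(512L))
  k <- c(0L, 0L)
  k[start_deme] <- 1L
  ex[[start_deme]][1L] <- 0L   # lineage whose parent is the origin
  tnow <- 0
  ev <- 0L
  pop_weighted <- identical(weighting, "population")
  repeat {
    if (k[1] + k[2] == 0L) return(NULL)                     # extinct
    done <- if (stop_rule == "total") sum(k) >= sum(targets)
            else k[1] >= targets[1] && k[2] >= targets[2]
    if (done) break
    ev <- ev + 1L
    if (ev > max_events) stop("runaway simulation: event guard exceeded")
    w1 <- if (k[1] > 0L) Ts[1] else 0
    w2 <- if (k[2] > 0L) Ts[2] else 0
    if (pop_weighted) { w1 <- k[1] * w1; w2 <- k[2] * w2 }
    i <- if (runif(1L) * (w1 + w2) <= w1) 1L else 2L
    tnow <- tnow + rexp(1L, k[i] * Ts[i])
    s <- runif(1L) * Ts[i]
    j <- sample.int(k[i], 1L)
    p <- ex[[i]][j]
    # create the node ending lineage (p -> new node) at time tnow
    nn <- nn + 1L
    if (nn > cap) {
      cap <- cap * 2L
      length(par) <- cap; length(tim) <- cap
      length(dem) <- cap; length(typ) <- cap
    }
    par[nn] <- p; tim[nn] <- tnow; dem[nn] <- i
    if (s <= lam[i]) {                                      # birth
      typ[nn] <- .BIF
      ex[[i]][j] <- nn
      k[i] <- k[i] + 1L
      if (k[i] > length(ex[[i]])) length(ex[[i]]) <- 2L * k[i]
      ex[[i]][k[i]] <- nn
    } else if (s <= lam[i] + alf[i]) {                      # migration
      typ[nn] <- .MIG
      ex[[i]][j] <- ex[[i]][k[i]]
      k[i] <- k[i] - 1L
      o <- 3L - i
      k[o] <- k[o] + 1L
      if (k[o] > length(ex[[o]])) length(ex[[o]]) <- 2L * k[o]
      ex[[o]][k[o]] <- nn
    } else {                                                # death
      typ[nn] <- .DEAD
      ex[[i]][j] <- ex[[i]][k[i]]
      k[i] <- k[i] - 1L
    }
  }
  # surviving lineages become extant tips at the time of the last event
  for (i in 1:2) {
    if (k[i] == 0L) next
    idx <- seq_len(k[i])
    m <- length(idx)
    while (nn + m > cap) {
      cap <- cap * 2L
      length(par) <- cap; length(tim) <- cap
      length(dem) <- cap; length(typ) <- cap
    }
    sl <- nn + idx
    par[sl] <- ex[[i]][idx]; tim[sl] <- tnow
    dem[sl] <- i; typ[sl] <- .TIP
    nn <- nn + m
  }
  list(par = par[seq_len(nn)], tim = tim[seq_len(nn)],
       dem = dem[seq_len(nn)], typ = typ[seq_len(nn)],
       n_events = ev, counts = k)
}

# Converts raw arrays to a crown phylo: prunes dead lineages, suppresses
# the unifurcations pruning creates (migration nodes are kept), trims the
# stem above the first surviving bifurcation, renumbers ape-style.
assemble_tree <- function(raw) {
  par <- raw$par; tim <- raw$tim; dem <- raw$dem; typ <- raw$typ
  nn <- length(par)
  keep <- typ == .TIP
  for (v in nn:1) if (keep[v] && par[v] > 0L) keep[par[v]] <- TRUE
  if (!any(keep)) stop("population extinct")
  ckept <- integer(nn)
  for (v in seq_len(nn)) if (keep[v] && par[v] > 0L)
    ckept[par[v]] <- ckept[par[v]] + 1L
  retained <- keep & !(typ == .BIF & ckept == 1L)
  # nearest retained ancestor
  anc <- integer(nn)
  for (v in seq_len(nn)) {
    p <- par[v]
    anc[v] <- if (p == 0L) 0L else if (retained[p]) p else anc[p]
  }
  rid <- which(retained)
  ch <- split(rid, anc[rid])
  root <- rid[anc[rid] == 0L]
  getch <- function(v) {
    x <- ch[[as.character(v)]]
    if (is.null(x)) integer(0) else x
  }
  while (length(getch(root)) == 1L) root <- getch(root)
  # DFS preorder from root over retained nodes
  ord <- integer(length(rid)); stack <- root; np <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    np <- np + 1L; ord[np] <- v
    kk <- getch(v)
    if (length(kk)) stack <- c(stack, rev(kk))
  }
  ord <- ord[seq_len(np)]
  tipold <- ord[typ[ord] == .TIP]
  intold <- ord[typ[ord] != .TIP]
  n <- length(tipold)
  newid <- integer(nn)
  newid[tipold] <- seq_len(n)                # tips numbered in preorder
  newid[intold] <- n + seq_along(intold)     # internals in preorder
  chv <- ord[ord != root]
  edge <- cbind(newid[anc[chv]], newid[chv])
  edge.length <- tim[chv] - tim[anc[chv]]
  deme <- integer(n + length(intold))
  deme[newid[ord]] <- dem[ord]
  phy <- structured_phylo(edge, tip.label = paste0("t", seq_len(n)),
                          edge.length = edge.length, deme = deme)
  phy
}

#' Simulate a structured two-deme birth-death-migration tree
#'
#' Runs the two-deme process from a single lineage until the configured
#' numbers of extant lineages are reached, then prunes extinct lineages and
#' returns the crown phylogeny with migration events as unifurcating
#' deme-change nodes.
#'
#' @param deme1,deme2 [deme_params()] for each deme.
#' @param n_tips integer length-2 vector of per-deme extant-lineage targets.
#' @param start_deme deme of the founding lineage (1 or 2).
#' @param stop_rule `"joint"` stops at the first event at which both demes
#'   have reached (or exceed) their targets; `"total"` stops when the total
#'   number of extant lineages first reaches `sum(n_tips)`.
#' @param weighting deme-selection weighting, see [select_deme()].
#' @param seed optional integer seed (set once before the first attempt).
#' @param max_events guard against runaway simulations.
#' @param max_retries restarts allowed after early extinction.
#' @return a `phylo` object with a per-node `deme` vector and a `sim_info`
#'   attribute (event count, retries, achieved per-deme tip counts,
#'   stop-rule interpretation).
#' @export
sim_bdm_tree <- function(deme1, deme2, n_tips = c(350L, 200L),
                         start_deme = 1L,
                         stop_rule = c("joint", "total"),
                         weighting = c("subtotal", "population"),
                         seed = NULL, max_events = 5e6, max_retries = 100L) {
  stop_rule <- match.arg(stop_rule)
  weighting <- match.arg(weighting)
  stopifnot(sum(n_tips) >= 2L, all(n_tips >= 0L), start_deme %in% 1:2)
  if (!is.null(seed)) set.seed(seed)
  r0 <- tryCatch(r0_general(deme1, deme2)$value, error = function(e) NA_real_)
  if (is.finite(r0) && r0 <= 1)
    warning("R0 <= 1: the process is subcritical and may rarely reach the ",
            "tip target", call. = FALSE)
  lam <- c(deme1$birth, deme2$birth)
  mu <- c(deme1$death, deme2$death)
  alf <- c(deme1$migration, deme2$migration)
  for (try in seq_len(max_retries)) {
    raw <- sim_attempt(lam, mu, alf, as.integer(start_deme),
                       as.integer(n_tips), stop_rule, weighting, max_events)
    if (!is.null(raw)) {
      phy <- assemble_tree(raw)
      attr(phy, "sim_info") <- list(
        n_events = raw$n_events, retries = try - 1L,
        counts = raw$counts, targets = as.integer(n_tips),
        stop_rule = stop_rule, start_deme = as.integer(start_deme),
        structured = TRUE)
      return(phy)
    }
  }
  stop("simulation failed: population went extinct in all ", max_retries,
       " attempts")
}

#' Simulate an unstructured birth-death tree
#'
#' Single-deme special case: a birth-death process without migration, run
#' until `n_tips` extant lineages, with extinct lineages pruned.
#'
#' @param birth,death per-lineage rates; a supercritical process requires
#'   `birth > death`.
#' @param n_tips number of extant tips of the returned tree.
#' @inheritParams sim_bdm_tree
#' @return a binary `phylo` object with `n_tips` tips and `n_tips - 1`
#'   internal nodes (all nodes labelled deme 1).
#' @export
sim_bd_tree <- function(birth, death = 0, n_tips, seed = NULL,
                        max_events = 5e6, max_retries = 100L) {
  stopifnot(n_tips >= 2L)
  if (birth <= death)
    warning("birth <= death: the process is subcritical", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_retries)) {
    raw <- sim_attempt(c(birth, birth), c(death, death), c(0, 0), 1L,
                       c(as.integer(n_tips), 0L), "joint", "subtotal",
                       max_events)
    if (!is.null(raw)) {
      phy <- assemble_tree(raw)
      attr(phy, "sim_info") <- list(
        n_events = raw$n_events, retries = try - 1L,
        counts = raw$counts, targets = c(as.integer(n_tips), 0L),
        stop_rule = "joint", start_deme = 1L, structured = FALSE)
      return(phy)
    }
  }
  stop("simulation failed: population went extinct in all ", max_retries,
       " attempts")
}

#' Prune dead tips from a rooted tree
#'
#' Removes the given tips, suppresses the unifurcations that the removal
#' creates (their branch lengths are merged), and keeps pre-existing
#' unifurcations such as migration nodes. When the removal leaves the root
#' with a single child because one of its clades died out entirely, the
#' former root is dropped and the surviving clade's base becomes the root.
#'
#' @param phy a `phylo` object, possibly with unifurcating migration nodes.
#' @param dead tip labels or tip indices to remove.
#' @return the pruned `phylo` object.
#' @export
prune_dead_tips <- function(phy, dead) {
  n <- n_tips(phy)
  if (is.character(dead)) dead <- match(dead, phy$tip.label)
  if (anyNA(dead) || any(dead < 1L | dead > n)) stop("unknown tip")
  if (length(dead) == 0L) return(phy)
  if (length(dead) >= n) stop("population extinct: all tips removed")
  ntot <- n + phy$Nnode
  par <- parent_vec(phy)
  nchild <- tabulate(phy$edge[, 1L], nbins = ntot)
  keep <- rep(TRUE, ntot)
  keep[dead] <- FALSE
  # drop internal nodes with no surviving descendants
  cnt <- integer(ntot)
  cnt[setdiff(seq_len(n), dead)] <- 1L
  for (v in rev(preorder_nodes(phy))) if (par[v] != 0L)
    cnt[par[v]] <- cnt[par[v]] + cnt[v]
  keep[cnt == 0L] <- FALSE
  ckept <- integer(ntot)
  for (v in which(keep)) if (par[v] != 0L && keep[par[v]])
    ckept[par[v]] <- ckept[par[v]] + 1L
  # suppress unifurcations created by pruning (originally >= 2 children)
  retained <- keep & !(nchild >= 2L & ckept == 1L & seq_len(ntot) > n)
  haslen <- !is.null(phy$edge.length)
  elen <- numeric(ntot)
  if (haslen) elen[phy$edge[, 2L]] <- phy$edge.length
  anc <- integer(ntot); anclen <- numeric(ntot)
  for (v in preorder_nodes(phy)) {
    p <- par[v]
    if (p == 0L) { anc[v] <- 0L; anclen[v] <- elen[v] }
    else if (retained[p]) { anc[v] <- p; anclen[v] <- elen[v] }
    else { anc[v] <- anc[p]; anclen[v] <- anclen[p] + elen[v] }
  }
  rid <- which(retained)
  ch <- split(rid, anc[rid])
  getch <- function(v) {
    x <- ch[[as.character(v)]]
    if (is.null(x)) integer(0) else x
  }
  root <- rid[anc[rid] == 0L]
  # drop a root whose other clade died out entirely
  while (root > n && length(getch(root)) == 1L && nchild[root] >= 2L)
    root <- getch(root)
  ord <- integer(length(rid)); stack <- root; np <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    np <- np + 1L; ord[np] <- v
    kk <- getch(v)
    if (length(kk)) stack <- c(stack, rev(kk))
  }
  ord <- ord[seq_len(np)]
  tipold <- ord[ord <= n]
  intold <- ord[ord > n]
  newid <- integer(ntot)
  newid[tipold] <- seq_along(tipold)
  newid[intold] <- length(tipold) + seq_along(intold)
  chv <- ord[ord != root]
  edge <- cbind(newid[anc[chv]], newid[chv])
  deme <- if (!is.null(phy$deme)) {
    d <- integer(length(ord)); d[newid[ord]] <- phy$deme[ord]; d
  } else NULL
  nlab <- if (!is.null(phy$node.label)) {
    l <- character(length(intold)); l[newid[intold] - length(tipold)] <-
      phy$node.label[intold - n]; l
  } else NULL
  structured_phylo(edge, tip.label = phy$tip.label[tipold],
                   edge.length = if (haslen) anclen[chv] else NULL,
                   deme = deme, node.label = nlab)
}
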