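# Labelled tree datasets.
#
# A dataset couples a set of non-structured (single-deme birth-death) trees
# with a set of structured (two-deme birth-death-migration) trees, both
# parameterised through R0: birth = R0 * death for the unstructured
# population, birth = R0 * (2*migration + death) per structured deme. R0
# and tip counts may be fixed or drawn per tree from intervals (uniformly,
# or by Latin hypercube sampling for the sensitivity designs). Every tree
# gets its own seed, dataset seed + replicate index, so any replicate can
# be regenerated in isolation.

#' Describe a simulated tree dataset
#'
#' Low-level constructor; see [baseline_config()] and friends for the
#' standard study designs. Entries `r0` and `n_tips` may be scalars or
#' length-2 intervals sampled per tree.
#'
#' @param name dataset name.
#' @param seed integer dataset seed.
#' @param unstructured list with `n_trees`, `death`, `r0`, `n_tips`.
#' @param structured list with `n_trees`, `deme1` and `deme2` (each a list
#'   of `death`, `migration`, `r0`, `n_tips`), `start_deme`, `stop_rule`.
#' @param sampling `"uniform"` or `"lhs"` for interval-valued entries.
#' @return a `dataset_config` list.
#' @export
dataset_config <- function(name, seed, unstructured, structured,
                           sampling = c("uniform", "lhs")) {
  sampling <- match.arg(sampling)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  cfg <- list(name = name, seed = as.integer(seed),
              unstructured = unstructured, structured = structured,
              sampling = sampling)
  class(cfg) <- "dataset_config"
  cfg
}

#' Baseline dataset design
#'
#' The reference design: 500 non-structured trees (death 0.014, R0 4.99,
#' 350 tips) and structured trees with deme 1 at death 0.014, migration
#' 0.3, R0 4.99, 350 tips and deme 2 at death 0.042, migration 0.2,
#' R0 9.09, 200 tips.
#'
#' @param seed dataset seed.
#' @param n_unstructured,n_structured tree counts per class.
#' @param tips_unstructured tip count (or interval) for non-structured
#'   trees.
#' @param tips_structured per-deme tip targets (or a list of two
#'   intervals).
#' @param stop_rule structured-tree termination rule, see [sim_bdm_tree()].
#' @param sampling see [dataset_config()].
#' @return a `dataset_config`.
#' @export
baseline_config <- function(seed = 1L, n_unstructured = 500L,
                            n_structured = 500L,
                            tips_unstructured = 350L,
                            tips_structured = list(350L, 200L),
                            stop_rule = "total",
                            sampling = "uniform") {
  if (!is.list(tips_structured)) tips_structured <- as.list(tips_structured)
  dataset_config(
    name = "baseline", seed = seed,
    unstructured = list(n_trees = n_unstructured, death = 0.014,
                        r0 = 4.99, n_tips = tips_unstructured),
    structured = list(
      n_trees = n_structured,
      deme1 = list(death = 0.014, migration = 0.3, r0 = 4.99,
                   n_tips = tips_structured[[1]]),
      deme2 = list(death = 3 * 0.014, migration = 0.2, r0 = 9.09,
                   n_tips = tips_structured[[2]]),
      start_deme = 1L, stop_rule = stop_rule),
    sampling = sampling)
}

#' Varied-tree-size dataset design
#'
#' Baseline rates with tip counts drawn per tree from intervals:
#' non-structured and deme 1 in (300, 400), deme 2 in `tips_deme2`
#' ((150, 250) for the second study dataset; the sensitivity design uses
#' (250, 300)).
#'
#' @inheritParams baseline_config
#' @param tips_deme2 interval for the deme-2 tip target.
#' @return a `dataset_config`.
#' @export
varied_size_config <- function(seed = 2L, n_unstructured = 500L,
                               n_structured = 500L,
                               tips_deme2 = c(150L, 250L),
                               stop_rule = "total",
                               sampling = "uniform") {
  baseline_config(seed = seed, n_unstructured = n_unstructured,
                  n_structured = n_structured,
                  tips_unstructured = c(300L, 400L),
                  tips_structured = list(c(300L, 400L), tips_deme2),
                  stop_rule = stop_rule, sampling = sampling)
}

#' Varied-parameters dataset design
#'
#' Baseline tip counts with per-tree deme R0 drawn from intervals
#' (0.45, 6.34) for deme 1 and (4.18, 36.75) for deme 2 (Latin hypercube
#' by default); death and migration rates stay at baseline, and so does the
#' non-structured population.
#'
#' @inheritParams baseline_config
#' @param r0_deme1,r0_deme2 R0 intervals for the structured demes.
#' @return a `dataset_config`.
#' @export
varied_parameters_config <- function(seed = 3L, n_unstructured = 500L,
                                     n_structured = 500L,
                                     r0_deme1 = c(0.45, 6.34),
                                     r0_deme2 = c(4.18, 36.75),
                                     stop_rule = "total",
                                     sampling = "lhs") {
  cfg <- baseline_config(seed = seed, n_unstructured = n_unstructured,
                         n_structured = n_structured,
                         stop_rule = stop_rule, sampling = sampling)
  cfg$name <- "varied-parameters"
  cfg$structured$deme1$r0 <- r0_deme1
  cfg$structured$deme2$r0 <- r0_deme2
  cfg
}

#' Varied size and parameters dataset design
#'
#' Combines [varied_size_config()] (sensitivity intervals) and
#' [varied_parameters_config()].
#'
#' @inheritParams varied_parameters_config
#' @inheritParams varied_size_config
#' @return a `dataset_config`.
#' @export
varied_both_config <- function(seed = 4L, n_unstructured = 500L,
                               n_structured = 500L,
                               tips_deme2 = c(250L, 300L),
                               r0_deme1 = c(0.45, 6.34),
                               r0_deme2 = c(4.18, 36.75),
                               stop_rule = "total",
                               sampling = "lhs") {
  cfg <- varied_parameters_config(seed = seed,
                                  n_unstructured = n_unstructured,
                                  n_structured = n_structured,
                                  r0_deme1 = r0_deme1, r0_deme2 = r0_deme2,
                                  stop_rule = stop_rule, sampling = sampling)
  cfg$name <- "varied-size-parameters"
  cfg$unstructured$n_tips <- c(300L, 400L)
  cfg$structured$deme1$n_tips <- c(300L, 400L)
  cfg$structured$deme2$n_tips <- tips_deme2
  cfg
}

is_interval <- function(x) length(x) == 2L

# draw the interval-valued entries of a spec list for n replicates;
# returns a data frame with one column per varied quantity
draw_varied <- function(quants, n, sampling) {
  varied <- Filter(function(q) is_interval(q$value), quants)
  if (!length(varied)) return(NULL)
  ivs <- lapply(varied, function(q) range(q$value))
  names(ivs) <- vapply(varied, function(q) q$name, character(1))
  if (sampling == "lhs") {
    d <- latin_hypercube_design(ivs, n)$samples
  } else {
    d <- as.data.frame(lapply(ivs, function(iv) runif(n, iv[1], iv[2])))
  }
  for (nm in names(d)) if (grepl("n_tips", nm)) d[[nm]] <- round(d[[nm]])
  d
}

#' Simulate a labelled tree dataset
#'
#' Simulates every replicate of a [dataset_config()]: non-structured trees
#' through [sim_bd_tree()], structured trees through [sim_bdm_tree()], with
#' per-tree seeds `seed + replicate` and per-tree draws of any
#' interval-valued R0 or tip-count entries. Optionally writes one Newick
#' file per tree plus a manifest table.
#'
#' @param config a `dataset_config`.
#' @param out_dir optional directory for Newick files and `manifest.csv`.
#' @param verbose print a progress line every 100 trees.
#' @return a list of class `ps_dataset`: `trees` (a `multiPhylo`),
#'   `manifest` (data frame with `replicate_id`, `label`, `n_tips`,
#'   `seed`, `newick_path`), and the `config`.
#' @export
simulate_dataset <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "dataset_config"))
  set.seed(config$seed)
  un <- config$unstructured
  st <- config$structured
  nu <- un$n_trees; ns <- st$n_trees
  udraw <- draw_varied(list(list(name = "r0", value = un$r0),
                            list(name = "n_tips", value = un$n_tips)),
                       nu, config$sampling)
  sdraw <- draw_varied(list(
    list(name = "r0_1", value = st$deme1$r0),
    list(name = "r0_2", value = st$deme2$r0),
    list(name = "n_tips_1", value = st$deme1$n_tips),
    list(name = "n_tips_2", value = st$deme2$n_tips)), ns, config$sampling)
  pick <- function(draws, col, i, fixed) {
    if (!is.null(draws) && col %in% names(draws)) draws[[col]][i] else fixed
  }
  trees <- vector("list", nu + ns)
  man <- vector("list", nu + ns)
  for (i in seq_len(nu)) {
    sd_i <- config$seed + i
    r0 <- pick(udraw, "r0", i, un$r0)
    nt <- pick(udraw, "n_tips", i, un$n_tips)
    trees[[i]] <- sim_bd_tree(birth_rate_for_r0(r0, un$death), un$death,
                              n_tips = nt, seed = sd_i)
    man[[i]] <- data.frame(replicate_id = paste0("unstr", i),
                           label = "non-structured",
                           n_tips = length(trees[[i]]$tip.label),
                           seed = sd_i, newick_path = NA_character_)
    if (verbose && i %% 100L == 0L)
      message("non-structured: ", i, "/", nu)
  }
  for (j in seq_len(ns)) {
    i <- nu + j
    sd_i <- config$seed + i
    r01 <- pick(sdraw, "r0_1", j, st$deme1$r0)
    r02 <- pick(sdraw, "r0_2", j, st$deme2$r0)
    nt1 <- pick(sdraw, "n_tips_1", j, st$deme1$n_tips)
    nt2 <- pick(sdraw, "n_tips_2", j, st$deme2$n_tips)
    d1 <- deme_params(birth_rate_for_r0(r01, st$deme1$death,
                                        st$deme1$migration),
                      st$deme1$death, st$deme1$migration)
    d2 <- deme_params(birth_rate_for_r0(r02, st$deme2$death,
                                        st$deme2$migration),
                      st$deme2$death, st$deme2$migration)
    trees[[i]] <- withCallingHandlers(
      sim_bdm_tree(d1, d2, n_tips = c(nt1, nt2),
                   start_deme = st$start_deme,
                   stop_rule = st$stop_rule, seed = sd_i),
      warning = function(w) invokeRestart("muffleWarning"))
    man[[i]] <- data.frame(replicate_id = paste0("str", j),
                           label = "structured",
                           n_tips = length(trees[[i]]$tip.label),
                           seed = sd_i, newick_path = NA_character_)
    if (verbose && j %% 100L == 0L)
      message("structured: ", j, "/", ns)
  }
  manifest <- do.call(rbind, man)
  class(trees) <- "multiPhylo"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, paste0(manifest$replicate_id, ".nwk"))
    for (i in seq_along(trees)) write_newick(trees[[i]], paths[i])
    manifest$newick_path <- paths
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  structure(list(trees = trees, manifest = manifest, config = config),
            class = "ps_dataset")
}

#' Shape-statistic table of a simulated dataset
#'
#' @param dataset a `ps_dataset` from [simulate_dataset()].
#' @return the [tree_stats_table()] of the dataset's trees, labelled from
#'   its manifest.
#' @export
dataset_stats <- function(dataset) {
  stopifnot(inherits(dataset, "ps_dataset"))
  tree_stats_table(dataset$trees, labels = dataset$manifest$label,
                   tree_id = dataset$manifest$replicate_id)
}
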