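test_that("waiting times are exponential with rate N * (birth+death+migration)", {
  p <- deme_params(1, 0.6, 0.4)   # subtotal rate 2 per lineage
  expect_error(waiting_time(0, p), "inactive")
  set.seed(1)
  draws <- replicate(1e5, waiting_time(1, p))
  expect_true(all(draws > 0))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
})

test_that("deme selection follows the sub-total-rate rule", {
  d1 <- deme_params(1, 0.5, 0.5)   # T1 = 2
  d2 <- deme_params(1, 0.5, 0.5)   # T2 = 2
  expect_equal(select_deme(c(5L, 1L), d1, d2, u = 0.25), 1L)
  expect_equal(select_deme(c(5L, 1L), d1, d2, u = 0.75), 2L)
  expect_error(select_deme(c(0L, 0L), d1, d2, u = 0.5), "extinct")
  # empirical frequency matches T1 / (T1 + T2) despite unequal populations
  d2b <- deme_params(4, 1, 1)      # T2 = 6, so P(deme 1) = 0.25
  set.seed(2)
  hits <- replicate(1e5, select_deme(c(10L, 2L), d1, d2b) == 1L)
  se <- sqrt(0.25 * 0.75 / length(hits))
  expect_lt(abs(mean(hits) - 0.25), 3 * se)
  # population weighting uses N_i * T_i instead
  set.seed(3)
  hits <- replicate(2e4, select_deme(c(10L, 2L), d1, d2b,
                                     weighting = "population") == 1L)
  p_exp <- 10 * 2 / (10 * 2 + 2 * 6)
  expect_lt(abs(mean(hits) - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 2e4))
})

test_that("event selection uses the cumulative rate thresholds", {
  p <- deme_params(3, 1, 1)   # birth 0.6, migration next 0.2, death 0.2
  expect_equal(select_event(p, sigma = 0), "birth")
  expect_equal(select_event(p, sigma = 0.6), "birth")
  expect_equal(select_event(p, sigma = 0.7), "migration")
  expect_equal(select_event(p, sigma = 0.80001), "death")
  expect_equal(select_event(p, sigma = 1), "death")
  expect_error(select_event(p, sigma = 1.5), "invalid")
})

test_that("unstructured trees hit the tip target with n-1 internal nodes", {
  for (n in c(2L, 10L, 73L)) {
    tr <- sim_bd_tree(1, 0.3, n, seed = n)
    expect_s3_class(tr, "phylo")
    expect_equal(length(tr$tip.label), n)
    expect_equal(tr$Nnode, n - 1L)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("structured trees respect deme labels, migration nodes and targets", {
  # no migration possible: all one deme, binary tree
  d <- deme_params(1, 0.2, 0)
  tr <- sim_bdm_tree(d, d, c(20L, 0L), seed = 4)
  expect_equal(length(tr$tip.label), 20L)
  expect_true(all(tr$deme == 1L))
  expect_equal(tr$Nnode, 19L)
  # with migration: unifurcations are deme changes; tips = target (total rule)
  tr <- sim_bdm_tree(hiv_deme1(), hiv_deme2(), c(30L, 20L), seed = 9,
                     stop_rule = "total")
  expect_equal(length(tr$tip.label), 50L)
  expect_gte(tr$Nnode, 49L)
  ch <- phylostruct:::children_list(tr)
  n <- length(tr$tip.label)
  for (v in (n + 1L):(n + tr$Nnode)) {
    k <- ch[[v]]
    if (length(k) == 1L) expect_true(tr$deme[k] != tr$deme[v])
    else expect_length(k, 2L)
  }
  # joint rule reaches both per-deme targets
  trj <- sim_bdm_tree(hiv_deme1(), hiv_deme2(), c(15L, 10L), seed = 10,
                      stop_rule = "joint")
  info <- attr(trj, "sim_info")
  expect_gte(info$counts[1], 15L)
  expect_gte(info$counts[2], 10L)
  expect_equal(length(trj$tip.label), sum(info$counts))
})

test_that("pure-birth structured runs have exactly n-1 bifurcations", {
  d1 <- deme_params(2, 0, 0.4)
  d2 <- deme_params(3, 0, 0.3)
  tr <- sim_bdm_tree(d1, d2, c(25L, 0L), seed = 12, stop_rule = "total")
  n <- length(tr$tip.label)
  ch <- phylostruct:::children_list(tr)
  nbif <- sum(vapply(ch, length, integer(1)) == 2L)
  expect_equal(n, 25L)
  expect_equal(nbif, n - 1L)
  expect_gte(tr$Nnode, n - 1L)
})

test_that("pruning removes dead tips, keeps migration nodes, preserves extant tips", {
  tr <- read_newick(text = "((a:1,b:1):1,c:2);")[[1]]
  expect_identical(prune_dead_tips(tr, integer(0)), tr)
  p <- prune_dead_tips(tr, "c")
  expect_equal(sort(p$tip.label), c("a", "b"))
  expect_equal(p$Nnode, 1L)
  expect_equal(sum(p$edge.length), 2)           # lengths survive splicing
  expect_error(prune_dead_tips(tr, c("a", "b", "c")), "extinct")
  # migration unifurcation survives pruning next to it
  tm <- read_newick(
    text = "(((x[&deme=2]:1)m[&deme=1]:1,y[&deme=1]:1):1,z[&deme=1]:3);")[[1]]
  pm <- prune_dead_tips(tm, "y")
  expect_equal(sort(pm$tip.label), c("x", "z"))
  expect_equal(pm$Nnode, 2L)                    # root + migration node kept
  # random trees: extant tip set unchanged
  set.seed(21)
  for (rep in 1:5) {
    tr <- random_tree(12)
    dead <- sample(tr$tip.label, 4)
    p <- prune_dead_tips(tr, dead)
    expect_setequal(p$tip.label, setdiff(tr$tip.label, dead))
  }
})

test_that("Yule trees have the expected cherry count (n/3)", {
  set.seed(31)
  ch <- replicate(200, count_cherries(sim_bd_tree(1, 0, 100L)))
  se <- sd(ch) / sqrt(length(ch))
  expect_lt(abs(mean(ch) - 100 / 3), 3 * se)
})

test_that("simulation is reproducible from its seed", {
  a <- sim_bdm_tree(hiv_deme1(), hiv_deme2(), c(20L, 10L), seed = 55,
                    stop_rule = "total")
  b <- sim_bdm_tree(hiv_deme1(), hiv_deme2(), c(20L, 10L), seed = 55,
                    stop_rule = "total")
  expect_identical(write_newick(a), write_newick(b))
  cfg <- baseline_config(seed = 8L, n_unstructured = 3L, n_structured = 3L,
                         tips_unstructured = 15L,
                         tips_structured = list(10L, 6L))
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(write_newick(d1$trees), write_newick(d2$trees))
  expect_identical(d1$manifest, d2$manifest)
})

test_that("subcritical parameters trigger a warning and extinction an error", {
  expect_warning(sim_bd_tree(0.5, 0.5, 5L, seed = 1), "subcritical")
  expect_error(
    suppressWarnings(sim_bd_tree(0.1, 0.5, 5L, seed = 1, max_retries = 3L)),
    "simulation failed")
  d <- deme_params(0.01, 2, 0)
  expect_error(
    suppressWarnings(sim_bdm_tree(d, d, c(50L, 0L), seed = 1,
                                  max_retries = 3L)),
    "simulation failed")
})

test_that("dataset generation follows its configured design", {
  cfg <- varied_size_config(seed = 6L, n_unstructured = 6L,
                            n_structured = 6L, tips_deme2 = c(8L, 12L))
  cfg$unstructured$n_tips <- c(20L, 30L)
  cfg$structured$deme1$n_tips <- c(10L, 15L)
  ds <- simulate_dataset(cfg)
  man <- ds$manifest
  expect_equal(nrow(man), 12L)
  expect_equal(sum(man$label == "structured"), 6L)
  un <- man$n_tips[man$label == "non-structured"]
  expect_true(all(un >= 20L & un <= 30L))
  expect_equal(man$seed, cfg$seed + seq_len(12L))
  # tip counts of every tree match the manifest
  expect_equal(vapply(ds$trees, function(t) length(t$tip.label), integer(1)),
               man$n_tips)
})
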