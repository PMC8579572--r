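test_that("the five-tip worked example reproduces every pinned value", {
  tr <- example_structured_tree()
  st <- tree_shape_stats(tr)
  expect_equal(st$n_tips, 5L)
  expect_equal(st$cherries, 2L)
  expect_equal(st$sackin, 14L)
  expect_equal(st$colless, 2L)
  expect_equal(st$total_cophenetic, 6)
  expect_equal(st$ladder_length, 0.2)
  expect_equal(st$max_depth, 3L)
  expect_equal(st$max_width, 4L)
  expect_equal(round(st$width_depth_ratio, 4), 1.3333)
  expect_equal(st$cherries_norm, 0.8)
  expect_equal(st$sackin_norm, 1)
  expect_equal(round(st$colless_norm, 4), 0.3333)
})

test_that("cherries, ladder and width behave on canonical small trees", {
  two <- read_newick(text = "(a,b);")[[1]]
  expect_equal(count_cherries(two), 1L)
  expect_equal(max_tree_width(two), 2L)
  expect_equal(width_depth_ratio(two), 2)
  b4 <- balanced_tree(4)
  expect_equal(count_cherries(b4), 2L)
  expect_equal(sackin_index(b4), 8L)
  expect_equal(colless_index(b4), 0L)
  expect_equal(total_cophenetic(b4), 2)
  expect_equal(ladder_length(b4), 0)
  expect_equal(max_tree_depth(b4), 2L)
  expect_equal(max_tree_width(b4), 4L)
  c5 <- caterpillar_tree(5)
  expect_equal(count_cherries(c5), 1L)
  expect_equal(sackin_index(c5), 14L)
  expect_equal(colless_index(c5), 6L)
  expect_equal(ladder_length(c5), 0.6)
  expect_equal(max_tree_depth(c5), 4L)
  c4 <- caterpillar_tree(4)
  expect_equal(total_cophenetic(c4), 4)
})

test_that("caterpillar and balanced trees attain the closed-form extremes", {
  for (n in c(6L, 9L, 16L)) {
    ct <- caterpillar_tree(n)
    st <- tree_shape_stats(ct)
    expect_equal(st$colless, (n - 1) * (n - 2) / 2)
    expect_equal(st$colless_norm, 1)
    expect_equal(st$sackin_norm, 1)
    expect_equal(st$total_cophenetic, choose(n, 3))
  }
  b16 <- balanced_tree(16)
  expect_equal(colless_index(b16), 0L)
  expect_equal(count_cherries(b16), 8L)
  expect_equal(tree_shape_stats(b16)$cherries_norm, 1)
})

test_that("total cophenetic and Sackin match the brute-force LCA oracle", {
  set.seed(99)
  for (n in 4:8) {
    for (rep in 1:5) {
      tr <- random_tree(n)
      expect_equal(total_cophenetic(tr), oracle_cophenetic(tr))
      expect_equal(sackin_index(tr), oracle_sackin(tr))
    }
  }
  # also on trees containing migration unifurcations
  for (rep in 1:5) {
    tr <- sim_bdm_tree(hiv_deme1(), hiv_deme2(), c(8L, 5L),
                       seed = 100 + rep, stop_rule = "total")
    expect_equal(total_cophenetic(tr), oracle_cophenetic(tr))
    expect_equal(sackin_index(tr), oracle_sackin(tr))
  }
})

test_that("statistics ignore child order and branch lengths", {
  set.seed(3)
  for (rep in 1:5) {
    tr <- random_tree(12)
    st1 <- tree_shape_stats(tr)
    mr <- mirror_tree(tr)
    expect_equal(tree_shape_stats(mr), st1)
    tr2 <- tr
    tr2$edge.length <- runif(nrow(tr$edge), 0.1, 10)
    expect_equal(tree_shape_stats(tr2), st1)
  }
})

test_that("node counts per depth sum to the total node count", {
  trees <- list(example_structured_tree(), caterpillar_tree(7),
                sim_bdm_tree(hiv_deme1(), hiv_deme2(), c(10L, 6L),
                             seed = 5, stop_rule = "total"))
  for (tr in trees) {
    d <- phylostruct:::node_depths(tr)
    expect_equal(sum(tabulate(d + 1L)), length(tr$tip.label) + tr$Nnode)
    expect_lte(count_cherries(tr), floor(length(tr$tip.label) / 2))
  }
})

test_that("degenerate inputs are rejected", {
  one <- read_newick(text = "(a,b);")[[1]]
  expect_error(normalise_stats(1, 1, 0, 2), "n >= 3")
  multi <- read_newick(text = "(a,b,c);")[[1]]
  expect_error(colless_index(multi), "non-binary")
  expect_error(width_depth_ratio(structured_phylo(
    matrix(c(2L, 1L), 1), tip.label = "a")), "zero depth")
})

test_that("the statistics record is internally consistent", {
  tr <- sim_bdm_tree(hiv_deme1(), hiv_deme2(), c(12L, 8L), seed = 77,
                     stop_rule = "total")
  st <- tree_shape_stats(tr)
  expect_equal(st$width_depth_ratio, st$max_width / st$max_depth)
  nm <- normalise_stats(st$cherries, st$sackin, st$colless, st$n_tips)
  expect_equal(st[names(nm)], nm)
})
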