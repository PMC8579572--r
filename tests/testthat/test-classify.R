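# shared small labelled dataset for the classification tests
make_features <- function(seed = 17L, n = 50L) {
  cfg <- baseline_config(seed = seed, n_unstructured = n, n_structured = n,
                         tips_unstructured = 60L,
                         tips_structured = list(40L, 25L))
  build_feature_matrix(dataset_stats(simulate_dataset(cfg)))
}

test_that("feature matrix has the canonical shape and rejects bad input", {
  feats <- make_features(n = 10L)
  expect_equal(dim(feats), c(20L, 9L))
  expect_identical(names(feats), c("label", feature_columns()))
  expect_s3_class(feats$label, "factor")
  st <- data.frame(tree_id = c("a", "a"), label = "structured")
  expect_error(build_feature_matrix(st), "missing columns")
  tr <- example_structured_tree()
  expect_error(
    tree_stats_table(list(tr, tr), labels = c("structured", "structured"),
                     tree_id = c("x", "x")),
    "duplicate")
  # the worked-example row carries its pinned statistic values
  tab <- tree_stats_table(tr, labels = "structured")
  fm <- build_feature_matrix(tab)
  expect_equal(fm$cherries_norm, 0.8)
  expect_equal(fm$sackin_norm, 1)
  expect_equal(fm$total_cophenetic, 6)
})

test_that("trapezoid AUC equals the concordance oracle and hits the extremes", {
  truth <- rep(c("structured", "non-structured"), each = 5)
  expect_equal(roc_auc(truth, c(rep(2, 5), rep(1, 5)))$auc, 1)
  expect_equal(roc_auc(truth, c(rep(1, 5), rep(2, 5)))$auc, 0)
  expect_error(roc_auc(rep("structured", 4), 1:4), "both classes")
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(6:25, 1)
    truth <- sample(c("structured", "non-structured"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- sample(1:5, n, replace = TRUE)   # many ties
    expect_equal(roc_auc(truth, scores)$auc, oracle_auc(truth, scores))
  }
  # random scores on a large sample sit near 1/2
  set.seed(24)
  truth <- rep(c("structured", "non-structured"), each = 500)
  expect_lt(abs(roc_auc(truth, runif(1000))$auc - 0.5), 0.05)
})

test_that("evaluate_predictions computes the confusion-matrix metrics", {
  truth <- rep(c("structured", "non-structured"), c(151, 156))
  pred <- truth
  pred[1] <- "non-structured"          # one FN
  pred[152:153] <- "structured"        # two FP
  ev <- evaluate_predictions(truth, pred)
  expect_equal(ev$accuracy, 304 / 307)
  expect_equal(ev$sensitivity, 150 / 151)
  expect_equal(ev$specificity, 154 / 156)
  expect_equal(sum(ev$confusion), 307)
  all_pos <- rep("structured", length(truth))
  expect_equal(evaluate_predictions(truth, all_pos)$specificity, 0)
  perfect <- evaluate_predictions(truth, truth)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1))
  expect_error(evaluate_predictions(truth, pred[-1]), "length mismatch")
})

test_that("grid tuning is deterministic and separates separable data", {
  feats <- make_features()
  f1 <- tune_and_train(feats, "knn", seed = 31L)
  f2 <- tune_and_train(feats, "knn", seed = 31L)
  expect_identical(f1$params, f2$params)
  expect_true(f1$params$k %in% c(3, 5, 7, 9, 11))
  # linearly separable toy data: svm-linear trains to perfection
  toy <- feats
  toy[, feature_columns()] <- 0
  toy$cherries_norm <- ifelse(toy$label == "structured", 1, -1) +
    rnorm(nrow(toy), sd = 0.01)
  fit <- tune_and_train(toy, "svm_linear", seed = 32L)
  expect_equal(as.character(predict(fit, toy)), as.character(toy$label))
  expect_error(tune_and_train(feats[feats$label == "structured", ], "knn"),
               "both classes")
})

test_that("stratified folds preserve the class ratio within one sample", {
  y <- factor(rep(c("non-structured", "structured"), c(37, 63)),
              levels = c("non-structured", "structured"))
  set.seed(41)
  fold <- phylostruct:::stratified_folds(y, 10L)
  for (f in 1:10) {
    expect_lte(abs(sum(fold == f & y == "structured") - 6.3), 1)
    expect_lte(abs(sum(fold == f & y == "non-structured") - 3.7), 1)
  }
})

test_that("cross-validation separates the simulated classes and is seeded", {
  feats <- make_features()
  ev1 <- kfold_cross_validate(feats, "svm_linear", k_folds = 5L, seed = 43L)
  ev2 <- kfold_cross_validate(feats, "svm_linear", k_folds = 5L, seed = 43L)
  expect_identical(ev1$per_fold, ev2$per_fold)
  expect_gt(ev1$means[["accuracy"]], 0.85)
  expect_equal(sum(ev1$confusion), nrow(feats))
  expect_equal(nrow(ev1$per_fold), 5L)
})

test_that("label permutation drives accuracy to chance and AUC to 1/2", {
  feats <- make_features()
  set.seed(47)
  feats$label <- sample(feats$label)
  ev <- kfold_cross_validate(feats, "knn", k_folds = 5L,
                             params = list(k = 5L), seed = 48L)
  expect_lt(abs(ev$means[["accuracy"]] - 0.5), 0.2)
  expect_lt(abs(ev$means[["auc"]] - 0.5), 0.2)
})

test_that("Latin hypercube designs stratify each dimension", {
  d <- latin_hypercube_design(list(a = c(0, 1), b = c(10, 20)), 10L,
                              seed = 51L)
  expect_equal(dim(d$samples), c(10L, 2L))
  expect_equal(sort(findInterval(d$samples$a, seq(0, 1, 0.1),
                                 rightmost.closed = TRUE)), 1:10)
  expect_equal(sort(findInterval(d$samples$b, seq(10, 20, 1),
                                 rightmost.closed = TRUE)), 1:10)
  d2 <- latin_hypercube_design(list(a = c(0, 1), b = c(10, 20)), 10L,
                               seed = 51L)
  expect_identical(d$samples, d2$samples)
  expect_error(latin_hypercube_design(list(a = c(1, 1)), 5L), "interval")
  # the sensitivity R0 intervals stay inside their ranges
  d3 <- latin_hypercube_design(list(r01 = c(0.45, 6.34),
                                    r02 = c(4.18, 36.75)), 50L, seed = 52L)
  expect_true(all(d3$samples$r01 >= 0.45 & d3$samples$r01 <= 6.34))
  expect_true(all(d3$samples$r02 >= 4.18 & d3$samples$r02 <= 36.75))
})

test_that("classify_trees labels held-out structured simulations as structured", {
  feats <- make_features()
  fit <- tune_and_train(feats, "svm_linear", seed = 53L)
  held <- lapply(1:20, function(i)
    sim_bdm_tree(hiv_deme1(), hiv_deme2(), c(40L, 25L), seed = 900 + i,
                 stop_rule = "total"))
  res <- classify_trees(fit, held)
  expect_equal(sum(res$proportions), 100)
  expect_gte(res$proportions[["structured"]], 90)
  empty <- classify_trees(fit, list())
  expect_equal(nrow(empty$labels), 0L)
  expect_null(empty$proportions)
})

test_that("sensitivity experiment runs each mode at the configured size", {
  se <- sensitivity_experiment(modes = "varied-size", models = "dt",
                               n_per_class = 8L, seed = 61L, k_folds = 4L)
  expect_equal(nrow(se$report), 1L)
  expect_equal(sum(se$evaluations[["varied-size"]][["dt"]]$confusion), 16L)
})
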