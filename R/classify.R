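# Structured vs non-structured tree classification.
#
# Feature vector: the three normalised balance statistics plus the five
# remaining raw statistics. Classifiers: k-nearest neighbours (class::knn),
# support vector machines with linear/polynomial/radial kernels
# (e1071::svm, cost fixed at 1), and CART decision trees (rpart).
# Features are standardised to zero mean / unit variance using statistics
# of the training data only; hyperparameters come from a cross-validated
# grid search. "structured" is the positive class throughout.

#' Canonical feature column order
#' @return character vector of the eight feature column names.
#' @export
feature_columns <- function() {
  c("cherries_norm", "sackin_norm", "colless_norm", "total_cophenetic",
    "ladder_length", "max_width", "max_depth", "width_depth_ratio")
}

CLASS_LEVELS <- c("non-structured", "structured")
POSITIVE <- "structured"

#' Build the classifier feature matrix from a statistics table
#'
#' @param stats_table data frame from [tree_stats_table()] with a `label`
#'   column holding `"structured"` / `"non-structured"`.
#' @return a data frame with columns `label` (factor, positive class
#'   `"structured"`) and the eight features, row names the tree ids.
#' @export
build_feature_matrix <- function(stats_table) {
  need <- c("tree_id", "label", feature_columns())
  miss <- setdiff(need, names(stats_table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(stats_table$tree_id)) stop("duplicate tree ids")
  feats <- stats_table[, feature_columns(), drop = FALSE]
  bad <- !stats::complete.cases(feats) | is.na(stats_table$label)
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing values rejected", call. = FALSE)
    feats <- feats[!bad, , drop = FALSE]
    stats_table <- stats_table[!bad, , drop = FALSE]
  }
  lab <- factor(as.character(stats_table$label), levels = CLASS_LEVELS)
  if (anyNA(lab)) stop("labels must be 'structured' or 'non-structured'")
  out <- cbind(data.frame(label = lab), feats)
  rownames(out) <- stats_table$tree_id
  out
}

# stratified fold assignment preserving the class ratio within +-1
stratified_folds <- function(label, k) {
  fold <- integer(length(label))
  for (lv in levels(label)) {
    idx <- which(label == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

default_grid <- function(model, X) {
  switch(model,
    knn = list(k = c(3L, 5L, 7L, 9L, 11L)),
    svm_linear = list(cost = 1),
    svm_poly = expand.grid(degree = 2:4, gamma = c(0.01, 0.1, 1),
                           coef0 = 1, cost = 1),
    svm_radial = {
      g0 <- median_heuristic_gamma(X)
      list(gamma = g0 * c(0.25, 1, 4), cost = 1)
    },
    dt = list(cp = c(0.001, 0.0028, 0.01, 0.028, 0.1)),
    stop("unknown model: ", model))
}

# 1 / (2 * median squared pairwise distance) on (at most 200) scaled rows
median_heuristic_gamma <- function(X) {
  m <- nrow(X)
  if (m > 200L) X <- X[seq(1L, m, length.out = 200L), , drop = FALSE]
  d2 <- stats::dist(X)^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) return(1 / ncol(X))
  1 / (2 * med)
}

scale_train <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

fit_one <- function(model, X, y, params) {
  switch(model,
    knn = list(train = X, y = y, k = params$k),
    svm_linear = e1071::svm(X, y, kernel = "linear", cost = params$cost,
                            scale = FALSE),
    svm_poly = e1071::svm(X, y, kernel = "polynomial",
                          degree = params$degree, gamma = params$gamma,
                          coef0 = params$coef0, cost = params$cost,
                          scale = FALSE),
    svm_radial = e1071::svm(X, y, kernel = "radial", gamma = params$gamma,
                            cost = params$cost, scale = FALSE),
    dt = rpart::rpart(y ~ ., data = data.frame(X, y = y),
                      method = "class",
                      control = rpart::rpart.control(cp = params$cp)))
}

# returns list(class = factor, score = numeric score for the positive class)
predict_one <- function(model, fit, X) {
  if (model == "knn") {
    pr <- class::knn(fit$train, X, fit$y, k = fit$k, prob = TRUE)
    win <- attr(pr, "prob")
    score <- ifelse(pr == POSITIVE, win, 1 - win)
    return(list(class = factor(pr, levels = CLASS_LEVELS), score = score))
  }
  if (model %in% c("svm_linear", "svm_poly", "svm_radial")) {
    pr <- predict(fit, X, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient the signed decision value so larger = more structured
    sgn <- if (grepl(paste0("^", POSITIVE, "/"), colnames(dv)[1])) 1 else -1
    return(list(class = factor(pr, levels = CLASS_LEVELS),
                score = sgn * as.numeric(dv[, 1])))
  }
  pm <- predict(fit, data.frame(X), type = "prob")
  cl <- predict(fit, data.frame(X), type = "class")
  list(class = factor(cl, levels = CLASS_LEVELS),
       score = pm[, POSITIVE])
}

grid_as_list <- function(grid) {
  if (is.data.frame(grid)) {
    lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
  } else {
    g <- do.call(expand.grid, grid)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  }
}

#' Grid-search and train a tree classifier
#'
#' Selects hyperparameters by stratified cross-validated accuracy over a
#' grid, then fits the chosen model on the full (standardised) data.
#'
#' @param features data frame from [build_feature_matrix()].
#' @param model one of `"knn"`, `"svm_linear"`, `"svm_poly"`,
#'   `"svm_radial"`, `"dt"`.
#' @param grid optional named list or data frame of hyperparameter
#'   candidates; defaults depend on the model (`cost` is fixed at 1 for
#'   all SVMs).
#' @param inner_folds folds for the tuning cross-validation.
#' @param seed optional integer seed controlling fold assignment.
#' @return an object of class `ps_classifier` holding the fitted model, the
#'   tuned hyperparameters, their cross-validated accuracy and the feature
#'   standardisation constants.
#' @export
tune_and_train <- function(features, model, grid = NULL, inner_folds = 5L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- features$label
  if (nlevels(droplevels(y)) < 2L) stop("need both classes to train")
  X <- as.matrix(features[, feature_columns()])
  if (is.null(grid)) grid <- default_grid(model, scale_train(X)$X)
  cand <- grid_as_list(grid)
  fold <- stratified_folds(y, inner_folds)
  acc <- vapply(cand, function(p) {
    correct <- 0L
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      sc <- scale_train(X[tr, , drop = FALSE])
      Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, sc$center), 2,
                   sc$scale, "/")
      fit <- fit_one(model, sc$X, y[tr], p)
      pr <- predict_one(model, fit, Xte)
      correct <- correct + sum(pr$class == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  best <- cand[[which.max(acc)]]
  sc <- scale_train(X)
  structure(list(model = model, params = best,
                 cv_accuracy = max(acc),
                 grid_accuracy = data.frame(
                   do.call(rbind, lapply(cand, as.data.frame)),
                   accuracy = acc),
                 center = sc$center, scale = sc$scale,
                 feature_cols = feature_columns(), levels = CLASS_LEVELS,
                 fit = fit_one(model, sc$X, y, best)),
            class = "ps_classifier")
}

#' @export
print.ps_classifier <- function(x, ...) {
  cat("phylostruct classifier:", x$model, "\n")
  cat("  tuned parameters:",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n")
  cat("  tuning CV accuracy:", round(x$cv_accuracy, 4), "\n")
  invisible(x)
}

#' Predict structured/non-structured labels
#'
#' @param object a `ps_classifier`.
#' @param newdata a feature data frame (from [build_feature_matrix()] or
#'   [tree_stats_table()]) or a matrix with the feature columns.
#' @param type `"class"` for labels, `"score"` for the positive-class score.
#' @param ... unused.
#' @return factor of labels or numeric scores.
#' @export
predict.ps_classifier <- function(object, newdata,
                                  type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(as.data.frame(newdata)[, object$feature_cols])
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  pr <- predict_one(object$model, object$fit, X)
  if (type == "class") pr$class else pr$score
}

#' Sensitivity, specificity, accuracy and confusion matrix
#'
#' `"structured"` is the positive class: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP).
#'
#' @param truth,predicted factors or characters with the class labels.
#' @param scores optional positive-class scores; when given, the AUC is
#'   included.
#' @return a list with `sensitivity`, `specificity`, `accuracy`, `auc`
#'   (or `NA`), and the 2x2 `confusion` matrix (truth in columns).
#' @export
evaluate_predictions <- function(truth, predicted, scores = NULL) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  truth <- factor(as.character(truth), levels = CLASS_LEVELS)
  predicted <- factor(as.character(predicted), levels = CLASS_LEVELS)
  cm <- table(predicted = predicted, truth = truth)
  tp <- cm[POSITIVE, POSITIVE]
  tn <- cm[CLASS_LEVELS[1], CLASS_LEVELS[1]]
  fp <- cm[POSITIVE, CLASS_LEVELS[1]]
  fn <- cm[CLASS_LEVELS[1], POSITIVE]
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / sum(cm),
       auc = if (is.null(scores)) NA_real_ else roc_auc(truth, scores)$auc,
       confusion = cm)
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds, plots true positive rate against false
#' positive rate, and integrates by the trapezoidal rule; the result equals
#' the rank-sum (concordance) formulation, with ties counted one half.
#'
#' @param truth class labels (`"structured"` positive).
#' @param scores numeric positive-class scores.
#' @return list with `auc` and `points` (data frame of fpr, tpr).
#' @export
roc_auc <- function(truth, scores) {
  truth <- factor(as.character(truth), levels = CLASS_LEVELS)
  pos <- truth == POSITIVE
  if (!any(pos) || all(pos)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  # collapse tied scores so the curve steps once per distinct threshold
  last <- rev(!duplicated(rev(scores[ord])))
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(auc = auc, points = data.frame(fpr = fpr, tpr = tpr))
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Splits the data into stratified folds; within each fold the features are
#' standardised on the training part, the model fitted and the held-out
#' part predicted. Hyperparameters are tuned once on the full data
#' beforehand (the default) or supplied explicitly.
#'
#' @inheritParams tune_and_train
#' @param k_folds number of folds (default 10).
#' @param params optional fixed hyperparameter list; when `NULL`,
#'   [tune_and_train()] chooses them first.
#' @param seed optional integer seed (controls tuning and fold assignment).
#' @return an object of class `classifier_evaluation`: data frame
#'   `per_fold`, named vector `means` (sensitivity, specificity, auc,
#'   accuracy), pooled `confusion` matrix, `params`, `model`.
#' @export
kfold_cross_validate <- function(features, model, k_folds = 10L,
                                 params = NULL, grid = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- features$label
  if (nrow(features) < k_folds) stop("fewer rows than folds")
  if (is.null(params)) {
    tuned <- tune_and_train(features, model, grid = grid)
    params <- tuned$params
  }
  X <- as.matrix(features[, feature_columns()])
  fold <- stratified_folds(y, k_folds)
  per <- vector("list", k_folds)
  cm <- NULL
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < 2L)
      stop("a class is absent from a training fold")
    sc <- scale_train(X[tr, , drop = FALSE])
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, sc$center), 2,
                 sc$scale, "/")
    fit <- fit_one(model, sc$X, y[tr], params)
    pr <- predict_one(model, fit, Xte)
    ev <- evaluate_predictions(y[!tr], pr$class, pr$score)
    per[[f]] <- data.frame(fold = f, sensitivity = ev$sensitivity,
                           specificity = ev$specificity, auc = ev$auc,
                           accuracy = ev$accuracy)
    cm <- if (is.null(cm)) ev$confusion else cm + ev$confusion
  }
  per <- do.call(rbind, per)
  structure(list(model = model, params = params, per_fold = per,
                 means = colMeans(per[, c("sensitivity", "specificity",
                                          "auc", "accuracy")]),
                 confusion = cm, k_folds = k_folds),
            class = "classifier_evaluation")
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, model %s\n", x$k_folds, x$model))
  cat("  mean metrics:\n")
  print(round(x$means, 4))
  cat("  pooled confusion matrix:\n")
  print(x$confusion)
  invisible(x)
}

#' Latin hypercube design over named intervals
#'
#' One stratified sample per equal-width bin and dimension, scaled into the
#' requested intervals (via [lhs::randomLHS()]).
#'
#' @param intervals named list of length-2 numeric ranges.
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return list of class `lhs_design`: `intervals`, `n`, and the `samples`
#'   data frame.
#' @export
latin_hypercube_design <- function(intervals, n, seed = NULL) {
  if (!length(intervals)) stop("no intervals given")
  ok <- vapply(intervals, function(iv)
    length(iv) == 2L && is.finite(iv[1]) && is.finite(iv[2]) &&
      iv[2] > iv[1], logical(1))
  if (!all(ok)) stop("each interval must be a finite increasing pair")
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(n, length(intervals))
  s <- mapply(function(col, iv) iv[1] + col * (iv[2] - iv[1]),
              as.data.frame(u), intervals)
  s <- as.data.frame(matrix(s, nrow = n))
  names(s) <- names(intervals)
  structure(list(intervals = intervals, n = n, samples = s),
            class = "lhs_design")
}

#' Classify a set of trees
#'
#' Computes the feature vector of each tree and applies a fitted
#' classifier, returning per-tree labels and the class proportions.
#'
#' @param classifier a `ps_classifier`.
#' @param trees a list of `phylo` objects, or a path to a Newick file.
#' @return list with `labels` (data frame tree_id, label, score) and
#'   `proportions` (percentages per class, summing to 100).
#' @export
classify_trees <- function(classifier, trees) {
  if (is.character(trees)) trees <- read_newick(trees)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees))
    return(list(labels = data.frame(tree_id = character(0),
                                    label = character(0),
                                    score = numeric(0)),
                proportions = NULL))
  st <- tree_stats_table(trees)
  cl <- predict(classifier, st, type = "class")
  sc <- predict(classifier, st, type = "score")
  prop <- 100 * table(factor(cl, levels = CLASS_LEVELS)) / length(cl)
  list(labels = data.frame(tree_id = st$tree_id, label = as.character(cl),
                           score = sc),
       proportions = prop)
}
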