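# End-to-end experiment orchestration and table I/O.

#' Write / read a shape-statistics table
#'
#' Comma-separated, UTF-8, header row, full double precision; rows keep
#' the order they were given in.
#'
#' @param records data frame from [tree_stats_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_statistics_table <- function(records, path) {
  if (!nrow(records)) stop("no records to write")
  num <- vapply(records, is.numeric, logical(1))
  out <- records
  for (j in which(num)) out[[j]] <- format(records[[j]], digits = 17,
                                           trim = TRUE, scientific = FALSE)
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_statistics_table
#' @export
read_statistics_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Configure a full experiment
#'
#' @param dataset a [dataset_config()] (or list of them, e.g. baseline plus
#'   the sensitivity designs).
#' @param models classifiers to evaluate, see [tune_and_train()].
#' @param k_folds cross-validation folds.
#' @param p_method p-value mode for the rank tests in the comparison stage.
#' @param seed seed for the classification stage.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(dataset = baseline_config(),
                              models = c("knn", "svm_linear", "svm_poly",
                                         "svm_radial", "dt"),
                              k_folds = 10L,
                              p_method = "asymptotic",
                              seed = 1L) {
  if (inherits(dataset, "dataset_config")) dataset <- list(dataset)
  structure(list(dataset = dataset, models = models,
                 k_folds = as.integer(k_folds), p_method = p_method,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run a full experiment: simulate, measure, compare, classify
#'
#' For every dataset in the configuration: simulates the trees, writes the
#' Newick files and the dataset manifest, computes and writes the
#' shape-statistics table, the distribution-comparison report and the
#' cross-validated classification report, then writes a run manifest
#' listing every produced file with the configuration hash.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print stage timings to stderr.
#' @return the run manifest (list), invisibly.
#' @export
run_experiment <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  note <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
                                             ...)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(rapply(config, unclass, how = "replace")),
                       cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  files <- c(config = cfg_path)
  cv_all <- NULL
  for (ds_cfg in config$dataset) {
    tag <- ds_cfg$name
    note("simulating dataset '", tag, "'")
    ds_dir <- file.path(out_dir, paste0("trees_", tag))
    ds <- simulate_dataset(ds_cfg, out_dir = ds_dir)
    files[paste0("manifest_", tag)] <- file.path(ds_dir, "manifest.csv")
    note("computing tree statistics")
    st <- dataset_stats(ds)
    f <- file.path(out_dir, paste0("stats_", tag, ".csv"))
    write_statistics_table(st, f)
    files[paste0("stats_", tag)] <- f
    note("comparing distributions")
    rep <- comparison_report(st, p_method = config$p_method)
    f <- file.path(out_dir, paste0("comparison_", tag, ".csv"))
    write.csv(rep, f, row.names = FALSE)
    files[paste0("comparison_", tag)] <- f
    feats <- build_feature_matrix(st)
    for (m in config$models) {
      note("cross-validating ", m)
      ev <- kfold_cross_validate(feats, m, k_folds = config$k_folds,
                                 seed = config$seed)
      cv_all <- rbind(cv_all,
                      data.frame(dataset = tag, model = m,
                                 t(ev$means),
                                 params = paste(names(ev$params),
                                                unlist(ev$params),
                                                sep = "=", collapse = ";")))
    }
  }
  f <- file.path(out_dir, "cv_report.csv")
  write.csv(cv_all, f, row.names = FALSE)
  files["cv_report"] <- f
  manifest <- list(
    package_version = as.character(utils::packageVersion("phylostruct")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    dataset_seeds = vapply(config$dataset, `[[`, integer(1), "seed"),
    files = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Sensitivity analysis of classifier robustness
#'
#' For each requested mode, simulates a dataset with Latin-hypercube-drawn
#' tree sizes and/or deme R0 values (250 structured plus 250 non-structured
#' trees by default), then evaluates the classifiers under stratified
#' k-fold cross-validation.
#'
#' @param modes subset of `"varied-size"`, `"varied-parameters"`, `"both"`.
#' @param models classifiers to evaluate.
#' @param n_per_class trees per class and mode.
#' @param seed base seed; each mode uses `seed + its position`.
#' @param k_folds cross-validation folds.
#' @param stop_rule structured-tree termination rule.
#' @return list with `report` (one row per mode and model) and
#'   `evaluations` (nested list of `classifier_evaluation`).
#' @export
sensitivity_experiment <- function(modes = c("varied-size",
                                             "varied-parameters", "both"),
                                   models = c("knn", "svm_linear",
                                              "svm_poly", "svm_radial",
                                              "dt"),
                                   n_per_class = 250L, seed = 1L,
                                   k_folds = 10L, stop_rule = "total") {
  modes <- match.arg(modes, several.ok = TRUE)
  report <- NULL
  evals <- list()
  for (im in seq_along(modes)) {
    mode <- modes[im]
    ms <- seed + im
    cfg <- switch(mode,
      "varied-size" = varied_size_config(
        seed = ms, n_unstructured = n_per_class,
        n_structured = n_per_class, tips_deme2 = c(250L, 300L),
        stop_rule = stop_rule, sampling = "lhs"),
      "varied-parameters" = varied_parameters_config(
        seed = ms, n_unstructured = n_per_class,
        n_structured = n_per_class, stop_rule = stop_rule),
      "both" = varied_both_config(
        seed = ms, n_unstructured = n_per_class,
        n_structured = n_per_class, stop_rule = stop_rule))
    ds <- simulate_dataset(cfg)
    feats <- build_feature_matrix(dataset_stats(ds))
    evals[[mode]] <- list()
    for (m in models) {
      ev <- kfold_cross_validate(feats, m, k_folds = k_folds, seed = ms)
      evals[[mode]][[m]] <- ev
      report <- rbind(report,
                      data.frame(mode = mode, model = m, t(ev$means)))
    }
  }
  list(report = report, evaluations = evals)
}
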