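#' Pipeline configuration
#'
#' One object holding every stage's settings for an end-to-end
#' experiment.  Sub-seeds for the generator, split, selector and model
#' are derived deterministically from the global `rng_seed` unless the
#' component configs set their own.
#'
#' @param generator A [generator_config()].
#' @param preprocess A [preprocess_spec()].
#' @param selector `"none"`, `"IWO"` or `"BChOA"`.
#' @param selector_config An [iwo_config()] / [bchoa_config()] matching
#'   `selector`; defaults are built when `NULL`.
#' @param model A [model_spec()].
#' @param split A [split_spec()].
#' @param task `"qualitative4"` (adulterant type) or `"quantitative16"`
#'   (type-by-level).
#' @param output_dir Optional directory for artifacts (tables, masks,
#'   logs); nothing is written when `NULL`.
#' @param rng_seed Global seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, preprocess = preprocess_spec("SG-MSC"),
                            selector = c("none", "IWO", "BChOA"),
                            selector_config = NULL, model = NULL,
                            split = NULL,
                            task = c("quantitative16", "qualitative4"),
                            output_dir = NULL, rng_seed = 1L) {
  selector <- match.arg(selector)
  task <- match.arg(task)
  rng_seed <- as.integer(rng_seed)
  if (is.null(generator)) generator <- generator_config(rng_seed = rng_seed)
  if (is.null(model)) model <- model_spec(rng_seed = rng_seed + 2L)
  if (is.null(split)) split <- split_spec(rng_seed = rng_seed + 1L)
  if (is.null(selector_config) && selector == "IWO") {
    selector_config <- iwo_config(rng_seed = rng_seed + 3L)
  }
  if (is.null(selector_config) && selector == "BChOA") {
    selector_config <- bchoa_config(rng_seed = rng_seed + 3L)
  }
  structure(list(generator = generator, preprocess = preprocess,
                 selector = selector, selector_config = selector_config,
                 model = model, split = split, task = task,
                 output_dir = output_dir, rng_seed = rng_seed),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Flat key-value representation mirroring the component config fields
#' (the endmember library stays at its defaults and is not serialized).
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  gen <- config$generator[setdiff(names(config$generator), "library")]
  lst <- list(task = config$task, rng_seed = config$rng_seed,
              selector = config$selector,
              generator = gen,
              preprocess = unclass(config$preprocess),
              model = unclass(config$model),
              split = unclass(config$split))
  if (!is.null(config$selector_config)) {
    lst$selector_config <- unclass(config$selector_config)
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sel_cfg <- NULL
  if (!is.null(y$selector_config)) {
    sel_cfg <- switch(y$selector,
                      IWO = do.call(iwo_config, y$selector_config),
                      BChOA = do.call(bchoa_config, y$selector_config))
  }
  pipeline_config(
    generator = do.call(generator_config, y$generator),
    preprocess = do.call(preprocess_spec, y$preprocess),
    selector = y$selector, selector_config = sel_cfg,
    model = do.call(model_spec, y$model),
    split = do.call(split_spec, y$split),
    task = y$task, rng_seed = y$rng_seed)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

write_confusion_csv <- function(cm, path) {
  df <- data.frame(true = rownames(cm), unclass(cm), check.names = FALSE)
  data.table::fwrite(df, path, eol = "\n")
}

#' Run one end-to-end adulteration-detection experiment
#'
#' Generate (or accept) data, split 8:2, preprocess with the training set
#' as the reference, optionally select wavelengths on the training set
#' only, train the classifier, and evaluate on the held-out prediction
#' set.  When `config$output_dir` is set, writes `metrics.csv`,
#' train/prediction confusion matrices, the selected-wavelength list and
#' CER trajectory (when a selector ran), `config.yaml` and a `log.txt`
#' echoing every defaulted parameter.  Identical configs and seeds yield
#' byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param data Optional [spectra_set()]; generated from
#'   `config$generator` when `NULL`.
#' @return List with `report_train` and `report_prediction`
#'   ([metrics()] reports), `confusion_train`, `confusion_prediction`,
#'   `selection` (`NULL` without a selector), `model`, and `config`.
#' @export
run_experiment <- function(config, data = NULL) {
  if (is.null(data)) {
    data <- with_stage("generate", generate_dataset(config$generator))
  }
  labels_all <- class_labels(data, config$task)
  sp <- with_stage("split",
                   split_dataset(data, config$split, labels = labels_all))
  pp <- with_stage("preprocess",
                   apply_preprocessing(sp$train, sp$prediction,
                                       config$preprocess))
  train <- pp$train; test <- pp$test
  lab_train <- labels_all[sp$train_idx]
  lab_test <- labels_all[sp$prediction_idx]

  selection <- NULL
  if (config$selector != "none") {
    selection <- with_stage("selection", switch(
      config$selector,
      IWO = iwo_select(train, config$selector_config, labels = lab_train),
      BChOA = bchoa_select(train, config$selector_config,
                           labels = lab_train)))
    train <- apply_mask(train, selection$mask)
    test <- apply_mask(test, selection$mask)
  }

  model <- with_stage("train",
                      train_classifier(train, config$model,
                                       labels = lab_train))
  classes <- sort(unique(labels_all))
  cm_train <- confusion(lab_train, predict(model, train), classes)
  cm_test <- confusion(lab_test, predict(model, test), classes)
  result <- list(report_train = metrics(cm_train),
                 report_prediction = metrics(cm_test),
                 confusion_train = cm_train,
                 confusion_prediction = cm_test,
                 selection = selection, model = model, config = config)

  if (!is.null(config$output_dir)) {
    with_stage("artifacts", write_experiment_artifacts(result))
  }
  result
}

write_experiment_artifacts <- function(result) {
  config <- result$config
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  met <- data.frame(
    set = c("train", "prediction"),
    accuracy = round_half_up(c(result$report_train$accuracy,
                               result$report_prediction$accuracy)),
    precision = round_half_up(c(result$report_train$precision,
                                result$report_prediction$precision)),
    specificity = round_half_up(c(result$report_train$specificity,
                                  result$report_prediction$specificity)))
  data.table::fwrite(met, out("metrics.csv"), eol = "\n")
  write_confusion_csv(result$confusion_train, out("confusion_train.csv"))
  write_confusion_csv(result$confusion_prediction,
                      out("confusion_prediction.csv"))
  if (!is.null(result$selection)) {
    data.table::fwrite(
      data.frame(wavelength_nm = sprintf(
        "%.3f", result$selection$selected_wavelengths)),
      out("selected_wavelengths.csv"), eol = "\n")
    data.table::fwrite(
      data.frame(iteration = seq_along(result$selection$cer_trajectory) - 1L,
                 best_cer = sprintf("%.6f",
                                    result$selection$cer_trajectory)),
      out("cer_trajectory.csv"), eol = "\n")
  }
  write_pipeline_config(config, out("config.yaml"))
  log_lines <- c(
    paste0("task: ", config$task),
    paste0("global seed: ", config$rng_seed),
    paste0("preprocessing: ", config$preprocess$method,
           " (SG window ", config$preprocess$sg_window,
           ", polyorder ", config$preprocess$sg_polyorder,
           "; MSC reference = ",
           if (identical(config$preprocess$msc_reference, "train_mean"))
             "training-set mean spectrum" else "explicit vector", ")"),
    paste0("selector: ", config$selector),
    paste0("model: ", config$model$algorithm,
           if (config$model$algorithm == "SVM")
             paste0(" (RBF kernel assumed; grid C {",
                    paste(config$model$svm_C_grid, collapse = ","),
                    "} x gamma {",
                    paste(config$model$svm_gamma_grid, collapse = ","),
                    "}, ", config$model$cv_folds,
                    "-fold CV; selected C=", result$model$best_C,
                    " gamma=", result$model$best_gamma, ")") else ""),
    paste0("split: ", config$split$train_fraction, " train fraction, ",
           if (config$split$stratified) "stratified" else "unstratified"),
    "defaulted parameters: SG window/order, MSC reference, SVM kernel and CV folds, selector population sizes and binarization threshold are package defaults where unspecified by the study design")
  writeLines(log_lines, out("log.txt"))
  invisible(config$output_dir)
}

#' Compare preprocessing methods on one dataset
#'
#' Runs [run_experiment()] for every preprocessing method (RAW, SG, SNV,
#' MSC, SG-MSC, SG-SNV) crossed with the requested classifier(s), on a
#' shared dataset and split, and tabulates train/prediction accuracy,
#' macro precision and macro specificity.
#'
#' @param config A [pipeline_config()] providing everything but the
#'   preprocessing method.
#' @param data Optional [spectra_set()] (generated once when `NULL`).
#' @param models Character vector of algorithms to include.
#' @return data.frame with one row per model x preprocessing method;
#'   written to `comparison.csv` under `config$output_dir` if set.
#' @export
compare_preprocessing <- function(config, data = NULL, models = "SVM") {
  methods <- c("RAW", "SG", "SNV", "MSC", "SG-MSC", "SG-SNV")
  if (is.null(data)) data <- generate_dataset(config$generator)
  rows <- list()
  for (alg in models) {
    for (m in methods) {
      cfg <- config
      cfg$output_dir <- NULL
      cfg$preprocess <- preprocess_spec(m, config$preprocess$sg_window,
                                        config$preprocess$sg_polyorder,
                                        config$preprocess$msc_reference)
      cfg$model$algorithm <- alg
      res <- run_experiment(cfg, data = data)
      rows[[length(rows) + 1L]] <- data.frame(
        model = alg, preprocessing = m,
        train_accuracy = round_half_up(res$report_train$accuracy),
        train_precision = round_half_up(res$report_train$precision),
        train_specificity = round_half_up(res$report_train$specificity),
        prediction_accuracy = round_half_up(res$report_prediction$accuracy),
        prediction_precision = round_half_up(res$report_prediction$precision),
        prediction_specificity = round_half_up(res$report_prediction$specificity))
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(tab, file.path(config$output_dir, "comparison.csv"),
                       eol = "\n")
  }
  tab
}

#' Compare wavelength selectors against the full spectrum
#'
#' Runs the quantitative (type-by-level) experiment with no selector,
#' IWO and BChOA on a shared dataset and split, and tabulates prediction
#' metrics together with the dimensionality reduction and relative
#' accuracy improvement of each selector over the full spectrum.
#'
#' @param config A [pipeline_config()]; its `selector` field is ignored.
#' @param data Optional [spectra_set()].
#' @param selectors Selectors to include alongside `"none"`.
#' @return data.frame with one row per selector; written to
#'   `selector_comparison.csv` under `config$output_dir` if set.
#' @export
compare_selectors <- function(config, data = NULL,
                              selectors = c("IWO", "BChOA")) {
  if (is.null(data)) data <- generate_dataset(config$generator)
  run_one <- function(sel) {
    cfg <- pipeline_config(generator = config$generator,
                           preprocess = config$preprocess,
                           selector = sel, model = config$model,
                           split = config$split, task = config$task,
                           rng_seed = config$rng_seed)
    run_experiment(cfg, data = data)
  }
  base <- run_one("none")
  n_full <- n_wavelengths(data)
  rows <- list(data.frame(
    selector = "FULL", n_wavelengths = n_full,
    prediction_accuracy = round_half_up(base$report_prediction$accuracy),
    prediction_precision = round_half_up(base$report_prediction$precision),
    prediction_specificity = round_half_up(base$report_prediction$specificity),
    reduction_pct = 0, accuracy_improvement_pct = 0))
  for (sel in selectors) {
    res <- run_one(sel)
    imp <- improvement_stats(base$report_prediction, res$report_prediction,
                             n_full, res$selection$n_selected)
    rows[[length(rows) + 1L]] <- data.frame(
      selector = sel, n_wavelengths = res$selection$n_selected,
      prediction_accuracy = round_half_up(res$report_prediction$accuracy),
      prediction_precision = round_half_up(res$report_prediction$precision),
      prediction_specificity = round_half_up(res$report_prediction$specificity),
      reduction_pct = imp$reduction_pct,
      accuracy_improvement_pct = imp$accuracy_improvement_pct)
  }
  tab <- do.call(rbind, rows)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(tab,
                       file.path(config$output_dir,
                                 "selector_comparison.csv"), eol = "\n")
  }
  tab
}
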