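#' Classifier specification
#'
#' The study's three classifiers: a grid-searched RBF-kernel support
#' vector machine (the model the analysis selects), plus backpropagation
#' neural network and random forest baselines.  The SVM grid is
#' `C in {1, 10, 100, 1000}` crossed with `gamma in {0.001, 0.01, 0.1, 1}`
#' (16 candidates), scored by k-fold cross-validated accuracy on the
#' training set.
#'
#' @param algorithm `"SVM"`, `"BP"` or `"RF"`.
#' @param svm_C_grid,svm_gamma_grid SVM hyperparameter grids.
#' @param cv_folds Cross-validation folds for the grid search.
#' @param bp_hidden Hidden-layer size of the BP network.
#' @param rf_trees Number of random-forest trees.
#' @param rng_seed Seed for fold assignment and the stochastic learners.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("SVM", "BP", "RF"),
                       svm_C_grid = c(1, 10, 100, 1000),
                       svm_gamma_grid = c(0.001, 0.01, 0.1, 1),
                       cv_folds = 5L, bp_hidden = 64L, rf_trees = 500L,
                       rng_seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(length(svm_C_grid) >= 1, length(svm_gamma_grid) >= 1,
            cv_folds >= 2)
  structure(list(algorithm = algorithm, svm_C_grid = svm_C_grid,
                 svm_gamma_grid = svm_gamma_grid,
                 cv_folds = as.integer(cv_folds),
                 bp_hidden = as.integer(bp_hidden),
                 rf_trees = as.integer(rf_trees),
                 rng_seed = as.integer(rng_seed)),
            class = "model_spec")
}

#' Train/prediction split specification
#'
#' @param train_fraction Fraction of samples in the training set (study
#'   design: 0.8, i.e. an 8:2 split).
#' @param stratified Preserve per-class proportions (to rounding).
#' @param rng_seed Seed for the random assignment.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, stratified = TRUE,
                       rng_seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction,
                 stratified = isTRUE(stratified),
                 rng_seed = as.integer(rng_seed)),
            class = "split_spec")
}

# Stratified index draw: for each class, round(frac * n_k) samples to the
# first set (at least 1, never all); unstratified uses floor(frac * n).
stratified_indices <- function(labels, fraction) {
  unlist(lapply(split(seq_along(labels), labels), function(idx) {
    k <- min(max(round(fraction * length(idx)), 1L), length(idx) - 1L)
    if (length(idx) == 1L) {
      stop("class '", labels[idx], "' has a single sample; ",
           "stratified splitting needs >= 2 per class")
    }
    sample(idx, k)
  }), use.names = FALSE)
}

#' Split a spectra set into training and prediction sets
#'
#' Disjoint and exhaustive; with stratification the per-class proportions
#' are preserved to rounding (800 samples at 0.8 give the study's
#' 640/160 split).  Unstratified splits use floor-to-train rounding.
#'
#' @param data A [spectra_set()].
#' @param spec A [split_spec()].
#' @param labels Class labels to stratify on; defaults to the finest
#'   (type-by-level) labels.
#' @return List with `train` and `prediction` spectra sets and the
#'   index vectors `train_idx`, `prediction_idx`.
#' @export
split_dataset <- function(data, spec = split_spec(),
                          labels = class_labels(data)) {
  n <- n_samples(data)
  if (any(table(labels) == 0)) stop("empty class in labels")
  set.seed(spec$rng_seed)
  train_idx <- if (spec$stratified) {
    if (any(table(labels) < 2)) {
      stop("stratified split needs >= 2 samples per class")
    }
    sort(stratified_indices(labels, spec$train_fraction))
  } else {
    sort(sample.int(n, floor(spec$train_fraction * n)))
  }
  pred_idx <- setdiff(seq_len(n), train_idx)
  list(train = subset_samples(data, train_idx),
       prediction = subset_samples(data, pred_idx),
       train_idx = train_idx, prediction_idx = pred_idx)
}

# Seeded stratified fold assignment for cross-validation.
cv_fold_ids <- function(labels, k) {
  folds <- integer(length(labels))
  for (idx in split(seq_along(labels), labels)) {
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Train a classifier on a spectra set
#'
#' For `"SVM"`, all `C x gamma` grid combinations are scored by
#' `cv_folds`-fold cross-validated accuracy on the training set and the
#' best (ties broken by grid order) is refit on all of it, with an RBF
#' kernel.  `"BP"` fits a single-hidden-layer network with L2 weight
#' decay; `"RF"` a random forest.  Features are standardized with
#' training-set statistics before SVM and BP (kernels and gradients are
#' scale-sensitive); RF uses raw features.
#'
#' @param train A [spectra_set()].
#' @param spec A [model_spec()].
#' @param labels Class labels; defaults to type-by-level labels.
#' @return An object of class `nir_model` holding the fit, the selected
#'   hyperparameters (`best_C`, `best_gamma`, `cv_table` for SVM), the
#'   standardization statistics and the training wavelength grid.
#' @export
train_classifier <- function(train, spec = model_spec(),
                             labels = class_labels(train)) {
  X <- train$reflectance
  if (!all(is.finite(X))) stop("non-finite features in training data")
  y <- factor(labels)
  if (nlevels(y) < 2) stop("training data must contain >= 2 classes")
  set.seed(spec$rng_seed)
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, `/`)

  handle <- list(algorithm = spec$algorithm, spec = spec,
                 wavelengths = train$wavelengths,
                 center = center, scale = scale_, levels = levels(y))
  if (spec$algorithm == "SVM") {
    grid <- expand.grid(C = spec$svm_C_grid, gamma = spec$svm_gamma_grid,
                        KEEP.OUT.ATTRS = FALSE)
    folds <- cv_fold_ids(y, spec$cv_folds)
    acc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(spec$cv_folds)) {
        tr <- folds != f
        if (all(tr)) next  # small classes can leave a fold empty
        fit <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], kernel = "radial",
                          cost = grid$C[g], gamma = grid$gamma[g],
                          scale = FALSE)
        pr <- stats::predict(fit, Xs[!tr, , drop = FALSE])
        correct <- correct + sum(pr == y[!tr])
      }
      acc[g] <- correct / length(y)
    }
    best <- which.max(acc)
    handle$best_C <- grid$C[best]
    handle$best_gamma <- grid$gamma[best]
    handle$cv_table <- cbind(grid, cv_accuracy = acc)
    handle$fit <- e1071::svm(Xs, y, kernel = "radial",
                             cost = grid$C[best], gamma = grid$gamma[best],
                             scale = FALSE)
  } else if (spec$algorithm == "BP") {
    handle$fit <- nnet::nnet(Xs, nnet::class.ind(y),
                             size = spec$bp_hidden, decay = 1e-3,
                             maxit = 200, softmax = TRUE, trace = FALSE,
                             MaxNWts = 1e6)
  } else {
    handle$fit <- randomForest::randomForest(X, y, ntree = spec$rf_trees)
  }
  class(handle) <- "nir_model"
  handle
}

#' Predict class labels for new spectra
#'
#' @param object A fitted [train_classifier()] model.
#' @param data A [spectra_set()] (or bare feature matrix) on the model's
#'   wavelength grid.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.nir_model <- function(object, data, ...) {
  X <- if (inherits(data, "spectra_set")) {
    if (!isTRUE(all.equal(data$wavelengths, object$wavelengths))) {
      stop("wavelength grid mismatch: model expects ",
           length(object$wavelengths), " wavelengths [",
           format(min(object$wavelengths)), ", ",
           format(max(object$wavelengths)), "] nm")
    }
    data$reflectance
  } else {
    as.matrix(data)
  }
  if (ncol(X) != length(object$wavelengths)) {
    stop("feature count ", ncol(X), " does not match the ",
         length(object$wavelengths), " training wavelengths")
  }
  if (nrow(X) == 0) return(character(0))
  if (object$algorithm == "RF") {
    return(as.character(stats::predict(object$fit, X)))
  }
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  if (object$algorithm == "SVM") {
    as.character(stats::predict(object$fit, Xs))
  } else {
    pr <- stats::predict(object$fit, Xs)
    object$levels[max.col(pr, ties.method = "first")]
  }
}
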