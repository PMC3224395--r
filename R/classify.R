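#' Stratified train/test split of a feature table
#'
#' Splits a feature table into disjoint, exhaustive training and testing
#' partitions. When stratified (the default), the overall test size is
#' `round(nrow * test_fraction)` allocated across classes by the
#' largest-remainder rule, so per-class test counts are proportional and
#' the total is exact (4,230 segments at fraction 0.1 give exactly 423
#' test segments). Reproducible under `seed`.
#'
#' @param features Feature table with a `label` column.
#' @param test_fraction Fraction held out for testing, in (0, 1).
#' @param seed Integer seed.
#' @param stratified Stratify by class (default `TRUE`). Every class must
#'   then have at least 2 instances.
#' @return List with elements `train` and `test` (feature tables).
#' @export
split_train_test <- function(features, test_fraction = 0.1, seed = 1L,
                             stratified = TRUE) {
  stopifnot(test_fraction > 0, test_fraction < 1, nrow(features) >= 2)
  n <- nrow(features)
  if (stratified) {
    classes <- sort(unique(features$label))
    counts <- vapply(classes, function(cl) sum(features$label == cl), integer(1))
    if (any(counts < 2)) {
      stop(
        "stratified split requires at least 2 instances per class; class ",
        classes[which(counts < 2)[1]], " has ", min(counts)
      )
    }
    n_test <- round(n * test_fraction)
    take <- allocate_proportional(n_test, counts)
    test_idx <- with_seed(seed, {
      unlist(lapply(seq_along(classes), function(i) {
        pos <- which(features$label == classes[i])
        if (take[i] == 0) integer(0) else sample(pos, take[i])
      }))
    })
  } else {
    n_test <- max(1L, round(n * test_fraction))
    test_idx <- with_seed(seed, sample(n, n_test))
  }
  test_idx <- sort(test_idx)
  list(
    train = features[-test_idx, , drop = FALSE],
    test = features[test_idx, , drop = FALSE]
  )
}

#' Standardize feature columns using training-set statistics
#'
#' Centers each feature column of the training set to mean 0 and scales it
#' to unit standard deviation, and applies the same statistics to any
#' other feature sets (so test data is scaled with training statistics
#' only — no leakage). A zero-spread feature column is centered and left
#' unscaled, with a warning.
#'
#' @param train Training feature table.
#' @param ... Further feature tables to scale with the training statistics.
#' @return List with `train`, one entry per extra set (named as passed),
#'   and the `center` and `scale` vectors.
#' @export
standardize_features <- function(train, ...) {
  feats <- setdiff(names(train), c("subject_id", "window_index", "label"))
  x <- feature_matrix(train, feats)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  zero <- !is.finite(scale) | scale == 0
  if (any(zero)) {
    warning(
      "zero-spread feature column(s) left unscaled: ",
      paste(feats[zero], collapse = ", ")
    )
    scale[zero] <- 1
  }
  apply_scaling <- function(df) {
    m <- feature_matrix(df, feats)
    m <- sweep(sweep(m, 2, center), 2, scale, `/`)
    df[, feats] <- m
    df
  }
  others <- list(...)
  out <- c(
    list(train = apply_scaling(train)),
    lapply(others, apply_scaling)
  )
  out$center <- center
  out$scale <- scale
  out
}

# Default hyperparameter grids: span the (0, 100] x (0, 3] search interval
# and include every (c, gamma) value the tuned per-subject models use.
default_c_grid <- function() c(1, 5, 10, 15, 25, 45, 70, 100)
default_gamma_grid <- function() {
  c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 0.9, 1.1, 1.2, 1.5, 2.4, 3.0)
}

#' Cross-validated grid search for RBF-SVM hyperparameters
#'
#' Evaluates every `(c, gamma)` grid point by stratified k-fold
#' cross-validation (default 8 folds) on the training set, using the same
#' fold assignment for every grid point. The cross-validation accuracy of
#' a grid point is the mean held-out-fold accuracy, in percent. The best
#' point maximizes CV accuracy; ties are broken toward smaller `c`, then
#' smaller `gamma`. Features are standardized internally (training-set
#' statistics) unless `standardize = FALSE`.
#'
#' @param train Training feature table.
#' @param c_grid Penalty-factor grid, values in (0, 100].
#' @param gamma_grid RBF kernel width grid, values in (0, 3].
#' @param folds Number of CV folds (default 8); every class must have at
#'   least `folds` instances.
#' @param seed Integer seed for the fold assignment.
#' @param standardize Standardize features before fitting.
#' @return A `semg_grid_search`: `grid` (data.frame `c`, `gamma`,
#'   `cv_accuracy`), `best` (list `c`, `gamma`), `cv_folds`.
#' @export
grid_search_cv <- function(train, c_grid = default_c_grid(),
                           gamma_grid = default_gamma_grid(),
                           folds = 8L, seed = 1L, standardize = TRUE) {
  stopifnot(folds >= 2, all(c_grid > 0), all(c_grid <= 100),
            all(gamma_grid > 0), all(gamma_grid <= 3))
  classes <- sort(unique(train$label))
  counts <- vapply(classes, function(cl) sum(train$label == cl), integer(1))
  if (any(counts < folds)) {
    stop(
      "class ", classes[which(counts < folds)[1]], " has fewer instances (",
      min(counts), ") than cross-validation folds (", folds, ")"
    )
  }
  if (standardize) train <- standardize_features(train)$train
  x <- feature_matrix(train)
  y <- train$label

  # Stratified fold assignment, shared across all grid points.
  fold_id <- integer(nrow(train))
  with_seed(seed, {
    for (cl in classes) {
      pos <- which(y == cl)
      fold_id[pos] <- sample(rep_len(seq_len(folds), length(pos)))
    }
  })

  grid <- expand.grid(c = c_grid, gamma = gamma_grid, KEEP.OUT.ATTRS = FALSE)
  grid$cv_accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    fold_acc <- numeric(folds)
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      fit <- svm_fit(x[!hold, , drop = FALSE], y[!hold], grid$c[g], grid$gamma[g])
      pred <- svm_predict_labels(fit, x[hold, , drop = FALSE])
      fold_acc[f] <- mean(pred == y[hold])
    }
    grid$cv_accuracy[g] <- 100 * mean(fold_acc)
  }
  best_row <- order(-grid$cv_accuracy, grid$c, grid$gamma)[1]
  structure(
    list(
      grid = grid,
      best = list(c = grid$c[best_row], gamma = grid$gamma[best_row]),
      cv_folds = as.integer(folds)
    ),
    class = "semg_grid_search"
  )
}

#' @export
print.semg_grid_search <- function(x, ...) {
  cat(sprintf(
    "<semg_grid_search> %d grid points, %d-fold CV; best c = %g, gamma = %g (%.2f%% CV accuracy)\n",
    nrow(x$grid), x$cv_folds, x$best$c, x$best$gamma, max(x$grid$cv_accuracy)
  ))
  invisible(x)
}

# Canonical one-vs-one RBF-SVM fit: rows sorted by label then feature
# values so the fit does not depend on input row order and prediction-vote
# ties resolve toward the lowest class id.
svm_fit <- function(x, y, cost, gamma) {
  ord <- do.call(order, c(list(y), as.data.frame(x)))
  e1071::svm(
    x = x[ord, , drop = FALSE],
    y = factor(y[ord], levels = sort(unique(y))),
    kernel = "radial", cost = cost, gamma = gamma, scale = FALSE
  )
}

svm_predict_labels <- function(fit, x) {
  if (nrow(x) == 0) {
    return(integer(0))
  }
  as.integer(as.character(stats::predict(fit, x)))
}

#' Train a one-vs-one multi-class RBF-SVM
#'
#' Fits the soft-margin RBF-kernel support vector machine (one binary
#' classifier per class pair, majority vote at prediction time) at the
#' given hyperparameters. Features are standardized with training-set
#' statistics, which are stored in the model and re-applied by
#' [predict.semg_svm()]. Deterministic given its inputs: training rows
#' are canonically ordered before fitting, so permuting the training set
#' leaves the model unchanged.
#'
#' @param train Training feature table (at least 2 classes).
#' @param params List with elements `c` (penalty factor, in (0, 100]) and
#'   `gamma` (RBF width, in (0, 3]), e.g. the `best` element of a
#'   [grid_search_cv()] result.
#' @param standardize Standardize features (default `TRUE`).
#' @return A `semg_svm` model.
#' @export
train_svm <- function(train, params, standardize = TRUE) {
  stopifnot(is.list(params), params$c > 0, params$gamma > 0)
  classes <- sort(unique(train$label))
  if (length(classes) < 2) stop("training set must contain at least 2 classes")
  feats <- setdiff(names(train), c("subject_id", "window_index", "label"))
  if (standardize) {
    sc <- standardize_features(train)
    train_s <- sc$train
    center <- sc$center
    scale <- sc$scale
  } else {
    train_s <- train
    center <- stats::setNames(rep(0, length(feats)), feats)
    scale <- stats::setNames(rep(1, length(feats)), feats)
  }
  fit <- svm_fit(feature_matrix(train_s, feats), train_s$label, params$c, params$gamma)
  structure(
    list(
      fit = fit,
      params = list(c = params$c, gamma = params$gamma),
      center = center,
      scale = scale,
      feature_names = feats,
      classes = classes
    ),
    class = "semg_svm"
  )
}

#' Predict gesture classes with a trained model
#'
#' Applies the model's stored scaling statistics to the new features and
#' predicts by majority vote over the pairwise classifiers (105 binary
#' problems for 15 classes); vote ties resolve toward the lowest class id.
#'
#' @param object A `semg_svm` from [train_svm()].
#' @param newdata Feature table or matrix with the model's 24 feature
#'   columns.
#' @param ... Unused.
#' @return Integer vector of predicted class ids.
#' @export
predict.semg_svm <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    if (ncol(newdata) != length(object$feature_names)) {
      stop(
        "feature dimension mismatch: model expects ",
        length(object$feature_names), " features, got ", ncol(newdata)
      )
    }
    colnames(newdata) <- object$feature_names
    x <- newdata
  } else {
    x <- feature_matrix(newdata, object$feature_names)
  }
  x <- sweep(sweep(x, 2, object$center), 2, object$scale, `/`)
  svm_predict_labels(object$fit, x)
}

#' @export
print.semg_svm <- function(x, ...) {
  cat(sprintf(
    "<semg_svm> %d classes, c = %g, gamma = %g, %d support vectors\n",
    length(x$classes), x$params$c, x$params$gamma, x$fit$tot.nSV
  ))
  invisible(x)
}
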