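#' @name pocketclass
#' @title Buried / borderline / surface pocket classification
#'
#' @description
#' A trainable predictor distinguishing buried, borderline and surface
#' binding pockets from the 20-descriptor feature table. The training
#' protocol is grid search with stratified k-fold cross-validation on
#' z-scored features; supported algorithms are a shallow neural network
#' (ANN), SVM, k-nearest neighbours, Gaussian naive Bayes and random
#' forest. Optional two-sample Kolmogorov-Smirnov feature filtering is
#' available but off by default (it is not part of the default protocol,
#' which uses all features).
NULL

.CLASS_LEVELS <- c("buried", "borderline", "surface")

#' Construct a labelled pocket-feature dataset
#'
#' @param features data frame / matrix of feature columns (the 20-feature
#'   schema, or any consistent numeric schema).
#' @param labels character/factor labels, subset of
#'   buried/borderline/surface (or the merged two-class labels).
#' @param ids optional row identifiers (default row number as character).
#' @return an `enz_dataset`.
#' @export
labeled_dataset <- function(features, labels, ids = NULL) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(labels))
  if (anyNA(features))
    stop_enzport("enzport_schema_error", "missing feature values in dataset")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), .CLASS_LEVELS)
  if (length(bad) > 0)
    stop_enzport("enzport_schema_error",
                 paste0("unknown labels: ", paste(bad, collapse = ", ")))
  lev <- .CLASS_LEVELS[.CLASS_LEVELS %in% labels]
  ids <- ids %||% as.character(seq_len(nrow(features)))
  structure(list(features = features,
                 labels = factor(labels, levels = lev),
                 ids = as.character(ids)),
            class = "enz_dataset")
}

#' @export
print.enz_dataset <- function(x, ...) {
  cat(sprintf("<enz_dataset> %d rows x %d features; classes: %s\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Read / write the training CSV schema
#'
#' Schema: `id` column, feature columns, `label` column.
#'
#' @param path CSV path.
#' @return an `enz_dataset`.
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "label") %in% names(df)))
    stop_enzport("enzport_schema_error", "dataset CSV needs id and label columns")
  feats <- df[, setdiff(names(df), c("id", "label")), drop = FALSE]
  labeled_dataset(feats, df$label, df$id)
}

#' @rdname read_dataset_csv
#' @param dataset an `enz_dataset`.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- cbind(data.frame(id = dataset$ids), dataset$features,
              data.frame(label = as.character(dataset$labels)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Kolmogorov-Smirnov feature filter
#'
#' A feature is kept when the two-sample KS test (sup-norm of the empirical
#' CDF difference, asymptotic p-value) rejects distributional equality for
#' at least one pair of classes at level `alpha`. Constant features have KS
#' statistic 0 against every class and are removed (with a message).
#'
#' @param dataset an `enz_dataset` with at least 2 classes.
#' @param alpha significance level (default 0.05).
#' @return character vector of selected feature names; the per-feature
#'   minimum p-value is attached as attribute `p_values`.
#' @export
ks_filter <- function(dataset, alpha = 0.05) {
  lev <- levels(dataset$labels)
  if (length(lev) < 2)
    stop_enzport("enzport_stratification_error", "KS filter needs >= 2 classes")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  pmin_feat <- vapply(names(dataset$features), function(f) {
    x <- dataset$features[[f]]
    if (stats::sd(x) == 0) return(1)
    min(vapply(pairs, function(pr) {
      suppressWarnings(stats::ks.test(x[dataset$labels == pr[1]],
                                      x[dataset$labels == pr[2]],
                                      exact = FALSE))$p.value
    }, numeric(1)))
  }, numeric(1))
  const <- vapply(dataset$features, function(x) stats::sd(x) == 0, logical(1))
  if (any(const))
    message("ks_filter: removed constant features: ",
            paste(names(which(const)), collapse = ", "))
  keep <- names(pmin_feat)[pmin_feat < alpha & !const]
  attr(keep, "p_values") <- pmin_feat
  keep
}

# deterministic stratified fold assignment from (seed, labels, ids)
.stratified_folds <- function(labels, ids, k, seed) {
  ord <- order(ids)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- ord[labels[ord] == lv]
      if (length(idx) < k)
        stop_enzport("enzport_stratification_error",
                     sprintf("class '%s' has %d rows, fewer than %d folds",
                             lv, length(idx), k))
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

.default_grid <- function(algorithm, p) {
  switch(algorithm,
         ANN = expand.grid(size = c(8, 16, 32), decay = c(1e-4, 1e-3)),
         SVM = expand.grid(cost = c(0.1, 1, 10), gamma = c(1 / p, 0.1)),
         KNN = expand.grid(k = c(1, 3, 5, 7, 9)),
         NaiveBayes = data.frame(laplace = 0),
         RandomForest = expand.grid(mtry = c(2, 4, 6), ntree = 300))
}

.fit_one <- function(algorithm, x, y, params, seed) {
  with_seed(seed, switch(
    algorithm,
    ANN = nnet::nnet(x, nnet::class.ind(y), size = params$size,
                     decay = params$decay, maxit = 300, softmax = TRUE,
                     trace = FALSE, MaxNWts = 5000),
    SVM = e1071::svm(x, y, cost = params$cost, gamma = params$gamma,
                     probability = TRUE),
    KNN = list(x = x, y = y, k = params$k),
    NaiveBayes = e1071::naiveBayes(x, y, laplace = params$laplace),
    RandomForest = randomForest::randomForest(x, y, mtry = min(params$mtry, ncol(x)),
                                              ntree = params$ntree)))
}

.predict_prob <- function(algorithm, fit, x, lev) {
  n <- nrow(x)
  pr <- switch(
    algorithm,
    ANN = {
      p <- predict(fit, x)
      if (is.null(dim(p))) p <- cbind(1 - p, p)
      p
    },
    SVM = {
      p <- attr(predict(fit, x, probability = TRUE), "probabilities")
      p[, lev, drop = FALSE]
    },
    KNN = {
      nn <- RANN::nn2(fit$x, x, k = min(fit$k, nrow(fit$x)))
      t(apply(nn$nn.idx, 1, function(ii)
        table(factor(fit$y[ii], levels = lev)) / length(ii)))
    },
    NaiveBayes = predict(fit, x, type = "raw"),
    RandomForest = predict(fit, x, type = "prob"))
  pr <- as.matrix(pr)
  if (is.null(colnames(pr)) || !all(lev %in% colnames(pr)))
    colnames(pr) <- lev
  pr <- pr[, lev, drop = FALSE]
  pr / pmax(rowSums(pr), 1e-12)
}

#' Train a pocket classifier
#'
#' Grid search over hyperparameters with stratified k-fold cross-validation
#' on z-scored features (standardization fitted on the training rows of
#' each fold); the best parameter set by mean CV accuracy (tie resolved to
#' the first grid row) is refit on the full training set. The seed fixes
#' the fold assignment and any stochastic initialization; fold assignment
#' depends only on the seed, the labels and the canonical id order.
#'
#' @param dataset an `enz_dataset`.
#' @param algorithm one of `"ANN"`, `"SVM"`, `"KNN"`, `"NaiveBayes"`,
#'   `"RandomForest"` (default ANN).
#' @param grid data frame of hyperparameter combinations (rows in
#'   preference order); defaults per algorithm.
#' @param cv_folds number of CV folds (default 5, at least 2).
#' @param seed integer RNG seed.
#' @return an `enz_classifier`: algorithm, chosen parameters, CV accuracy
#'   table, scaler, levels, feature schema and the refit model.
#' @export
train_classifier <- function(dataset,
                             algorithm = c("ANN", "SVM", "KNN", "NaiveBayes",
                                           "RandomForest"),
                             grid = NULL, cv_folds = 5, seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(cv_folds >= 2)
  if (nlevels(dataset$labels) < 2)
    stop_enzport("enzport_stratification_error",
                 "training needs at least 2 classes")
  x <- as.matrix(dataset$features)
  y <- dataset$labels
  lev <- levels(y)
  grid <- grid %||% .default_grid(algorithm, ncol(x))
  if (is.null(grid) || nrow(grid) == 0)
    stop_enzport("enzport_config_error", "empty hyperparameter grid")
  folds <- .stratified_folds(y, dataset$ids, cv_folds, seed)

  cv_acc <- vapply(seq_len(nrow(grid)), function(gi) {
    accs <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f; te <- !tr
      if (length(unique(y[tr])) < length(lev))
        stop_enzport("enzport_stratification_error",
                     "a class is absent from a training fold")
      ctr <- colMeans(x[tr, , drop = FALSE])
      sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- scale(x[tr, , drop = FALSE], ctr, sdv)
      xte <- scale(x[te, , drop = FALSE], ctr, sdv)
      fit <- .fit_one(algorithm, xtr, y[tr], grid[gi, , drop = FALSE],
                      seed + 1000L * f + gi)
      pr <- .predict_prob(algorithm, fit, xte, lev)
      pred <- lev[max.col(pr, ties.method = "first")]
      mean(pred == as.character(y[te]))
    }, numeric(1))
    mean(accs)
  }, numeric(1))

  best <- which.max(cv_acc) # which.max takes the first maximum: grid order
  ctr <- colMeans(x); sdv <- apply(x, 2, stats::sd); sdv[sdv == 0] <- 1
  fit <- .fit_one(algorithm, scale(x, ctr, sdv), y,
                  grid[best, , drop = FALSE], seed)
  structure(list(
    algorithm = algorithm, params = grid[best, , drop = FALSE],
    cv_accuracy = data.frame(grid, cv_accuracy = cv_acc),
    center = ctr, scale = sdv, levels = lev,
    features = colnames(x), fit = fit, seed = seed
  ), class = "enz_classifier")
}

#' @export
print.enz_classifier <- function(x, ...) {
  cat(sprintf("<enz_classifier> %s (%s); CV accuracy %.3f; classes: %s\n",
              x$algorithm,
              paste(sprintf("%s=%g", names(x$params), unlist(x$params)),
                    collapse = ", "),
              max(x$cv_accuracy$cv_accuracy), paste(x$levels, collapse = "/")))
  invisible(x)
}

#' Predict pocket classes
#'
#' @param model an `enz_classifier`.
#' @param features a named feature vector, or a data frame / matrix of rows
#'   matching the training schema.
#' @return data frame with `label` (argmax probability; ties resolve in the
#'   fixed buried < borderline < surface order) and one probability column
#'   per class (rows sum to 1).
#' @export
predict_class <- function(model, features) {
  if (is.null(dim(features))) features <- t(as.matrix(features))
  features <- as.data.frame(features)
  if (!all(model$features %in% names(features)))
    stop_enzport("enzport_schema_error",
                 "feature schema does not match the trained model")
  x <- scale(as.matrix(features[, model$features, drop = FALSE]),
             model$center, model$scale)
  pr <- .predict_prob(model$algorithm, model$fit, x, model$levels)
  lab <- model$levels[max.col(pr, ties.method = "first")]
  out <- data.frame(label = factor(lab, levels = model$levels))
  out[model$levels] <- pr
  out
}

#' Classification metrics from a confusion matrix
#'
#' Confusion orientation: rows are truth, columns predictions. FPR of class
#' c is FP_c / (FP_c + TN_c); for convenience `one_minus_fpr` is also
#' reported (customarily highlighted for the buried class).
#'
#' @param confusion square integer matrix with identical row/column names.
#' @return a `Metrics` list: `accuracy`, per-class `precision`, `recall`,
#'   `fpr`, `one_minus_fpr`, `f1`, `macro_f1`, `confusion`, `n_test`.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  n <- sum(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- n - tp - fp - fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  fpr <- ifelse(fp + tn > 0, fp / (fp + tn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(accuracy = sum(tp) / n, precision = precision, recall = recall,
       fpr = fpr, one_minus_fpr = 1 - fpr, f1 = f1, macro_f1 = mean(f1),
       confusion = confusion, n_test = n)
}

#' Evaluate a classifier on a labelled test set
#'
#' @param model an `enz_classifier`.
#' @param testset an `enz_dataset` (non-empty, same feature schema).
#' @return a `Metrics` list, see [metrics_from_confusion()].
#' @export
evaluate <- function(model, testset) {
  stopifnot(nrow(testset$features) > 0)
  pred <- predict_class(model, testset$features)$label
  truth <- factor(as.character(testset$labels), levels = model$levels)
  conf <- table(truth = truth, predicted = factor(pred, levels = model$levels))
  metrics_from_confusion(unclass(conf))
}

#' Merge buried and borderline into one class
#'
#' Two-class variant of the problem: buried and borderline become a single
#' buried-like class (labelled `"buried"`); surface rows are unchanged; row
#' count and order preserved.
#'
#' @param dataset a three-class (or fewer) `enz_dataset`.
#' @return the merged `enz_dataset`.
#' @export
merge_two_class <- function(dataset) {
  lab <- as.character(dataset$labels)
  lab[lab %in% c("buried", "borderline")] <- "buried"
  labeled_dataset(dataset$features, lab, dataset$ids)
}

#' Write metrics as JSON
#'
#' @param metrics a `Metrics` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  m <- metrics
  m$confusion <- as.data.frame(as.table(m$confusion))
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
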