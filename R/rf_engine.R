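#' Train a probability classifier with feature importances
#'
#' The working classifier behind the pipeline: a random forest by default
#' (500 trees, `mtry = floor(sqrt(p))`, Gini/impurity importances, seeded
#' determinism), with gradient-boosted trees (`engine = "xgb"`) available
#' as a comparator behind the same contract.
#'
#' @param X Numeric feature matrix (samples x features, named columns).
#' @param y Two-class factor (or coercible); the second level is the
#'   positive class.
#' @param params List of engine parameters: `engine` ("rf" or "xgb"),
#'   `num_trees` (default 500), `mtry` (default `floor(sqrt(p))`),
#'   `seed`, and for xgb `max_depth`, `eta`.
#' @return A `flgarf_model` with `$predict_prob(newX)` (positive-class
#'   probability) and `$importance` (non-negative, one per feature).
#' @export
train_rf <- function(X, y, params = list()) {
  stopifnot(is.matrix(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.factor(y)
  if (nlevels(y) < 2) stop("y must contain two classes")
  engine <- params$engine %||% "rf"
  seed <- params$seed %||% 1
  num_trees <- params$num_trees %||% 500
  if (engine == "rf") {
    mtry <- params$mtry %||% max(1, floor(sqrt(ncol(X))))
    fit <- ranger::ranger(x = X, y = y, num.trees = num_trees,
                          mtry = min(mtry, ncol(X)),
                          probability = TRUE, importance = "impurity",
                          num.threads = 1, seed = derive_seed(seed, "rf"))
    pos <- levels(y)[2]
    structure(list(
      engine = "rf", fit = fit, levels = levels(y), features = colnames(X),
      importance = fit$variable.importance,
      predict_prob = function(newX) {
        pr <- stats::predict(fit, data = newX, num.threads = 1)$predictions
        pr[, pos]
      }), class = "flgarf_model")
  } else if (engine == "xgb") {
    if (!requireNamespace("xgboost", quietly = TRUE))
      stop("xgboost not available")
    lab <- as.integer(y == levels(y)[2])
    set.seed(derive_seed(seed, "rf"))
    fit <- xgboost::xgboost(
      data = X, label = lab, nrounds = params$nrounds %||% 50,
      max_depth = params$max_depth %||% 3, eta = params$eta %||% 0.2,
      gamma = params$gamma %||% 0.01, subsample = params$subsample %||% 0.5,
      colsample_bytree = params$colsample_bytree %||% 0.75,
      min_child_weight = params$min_child_weight %||% 1,
      objective = "binary:logistic", verbose = 0, nthread = 1)
    imp <- tryCatch({
      it <- xgboost::xgb.importance(model = fit)
      v <- stats::setNames(rep(0, ncol(X)), colnames(X))
      v[it$Feature] <- it$Gain
      v
    }, error = function(e) stats::setNames(rep(0, ncol(X)), colnames(X)))
    structure(list(
      engine = "xgb", fit = fit, levels = levels(y), features = colnames(X),
      importance = imp,
      predict_prob = function(newX) stats::predict(fit, newX)),
      class = "flgarf_model")
  } else stop("unknown engine: ", engine)
}

#' @export
print.flgarf_model <- function(x, ...) {
  cat(sprintf("<flgarf_model> engine=%s, %d features, positive class '%s'\n",
              x$engine, length(x$features), x$levels[2]))
  invisible(x)
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `folds` folds with class proportions
#' preserved, so every fold contains both classes whenever the minority
#' class has at least `folds` members.
#'
#' @param y Class labels.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer fold id per sample.
#' @export
cv_folds <- function(y, folds = 10, seed = 1) {
  if (folds < 2) stop("folds must be >= 2")
  y <- as.factor(y)
  set.seed(derive_seed(seed, "cv"))
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validated AUROC
#'
#' The study's 10-fold, 3-repeat scheme: for every repeat a fresh
#' stratified folding, a model fit on each training complement (optionally
#' after SMOTE rebalancing of that training fold only), and AUROC measured
#' on the held-out fold.
#'
#' @inheritParams train_rf
#' @param folds,repeats CV geometry (defaults 10 and 3).
#' @param smote Logical; rebalance each training fold with SMOTE.
#' @param seed Integer seed controlling folding, SMOTE and model fits.
#' @return List with `mean_auroc` and the `folds x repeats` vector
#'   `fold_aurocs`.
#' @export
repeated_cv_auroc <- function(X, y, folds = 10, repeats = 3, params = list(),
                              smote = FALSE, seed = 1) {
  y <- as.factor(y)
  if (min(table(y)) < folds)
    warning("minority class smaller than fold count; some folds may lack a class")
  out <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- cv_folds(y, folds, seed = seed * 131 + r)
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- fold == f
      if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
        warning("fold without both classes skipped")
        next
      }
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      if (smote) {
        sb <- smote_balance(Xtr, ytr, seed = seed * 131 + r * 17 + f)
        Xtr <- sb$X; ytr <- sb$y
      }
      fit <- train_rf(Xtr, ytr, params = c(params, list(seed = seed * 131 + r * 17 + f)))
      out <- c(out, auroc(fit$predict_prob(X[te, , drop = FALSE]), y[te]))
    }
  }
  list(mean_auroc = mean(out), fold_aurocs = out)
}

#' Gini-importance sequential feature curve
#'
#' Ranks all features once by the Gini importance of a model fit on the
#' full feature set, then refits on the top-k features for each requested
#' k, reporting the repeated-CV AUROC (and, when a test set is supplied, a
#' held-out test AUROC from a model refit on all training samples).
#'
#' @inheritParams repeated_cv_auroc
#' @param ks Feature counts to evaluate (default the study's
#'   2, 4, 8, 12, 16, 24, 32); ks beyond `ncol(X)` are skipped with a
#'   warning.
#' @param X_test,y_test Optional held-out test set.
#' @return Data frame with one row per k: `k`, `cv_auroc`, and `test_auroc`
#'   when a test set was given; the ranking is attached as attribute
#'   `"ranking"`.
#' @export
sequential_feature_curve <- function(X, y, ks = c(2, 4, 8, 12, 16, 24, 32),
                                     folds = 10, repeats = 3,
                                     params = list(), smote = FALSE, seed = 1,
                                     X_test = NULL, y_test = NULL) {
  drop_ks <- ks > ncol(X)
  if (any(drop_ks)) {
    warning("skipping k > feature count: ", paste(ks[drop_ks], collapse = ", "))
    ks <- ks[!drop_ks]
  }
  full <- train_rf(X, y, params = c(params, list(seed = seed)))
  # ties broken by feature id order for determinism
  ranking <- names(sort(-full$importance, method = "radix"))
  rows <- lapply(ks, function(k) {
    feats <- ranking[seq_len(k)]
    cv <- repeated_cv_auroc(X[, feats, drop = FALSE], y, folds = folds,
                            repeats = repeats, params = params,
                            smote = smote, seed = seed + k)
    test_auc <- NA_real_
    if (!is.null(X_test)) {
      fit <- train_rf(X[, feats, drop = FALSE], y,
                      params = c(params, list(seed = seed + k)))
      test_auc <- auroc(fit$predict_prob(X_test[, feats, drop = FALSE]), y_test)
    }
    data.frame(k = k, cv_auroc = cv$mean_auroc, test_auroc = test_auc)
  })
  out <- do.call(rbind, rows)
  attr(out, "ranking") <- ranking
  out
}
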