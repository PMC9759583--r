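#' Stratified train/test split
#'
#' Randomly partitions samples into training and test sets with the
#' training proportion enforced within each class (to +/- 1 sample).
#'
#' @param labels Class label per sample (>= 2 per class).
#' @param train_fraction Training proportion (default 0.8).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  labels <- as.factor(labels)
  if (any(table(labels) < 2))
    stop("every class needs at least 2 samples to split")
  set.seed(derive_seed(seed, "split"))
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1, min(length(idx) - 1, round(train_fraction * length(idx))))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Fit / apply the zero-variance + center + scale preprocessing
#'
#' Drops training columns with zero variance and z-scores the remainder
#' with TRAINING means and SDs; test data are transformed with the same
#' statistics, never their own.
#'
#' @param X Numeric training matrix (samples x features).
#' @return A `preprocess_model` with `kept`, `center`, `scale`.
#' @export
fit_preprocess <- function(X) {
  stopifnot(is.matrix(X), is.numeric(X))
  sds <- apply(X, 2, stats::sd)
  kept <- which(sds > 0)
  if (length(kept) == 0) stop("all columns are zero-variance")
  structure(list(kept = colnames(X)[kept] %||% kept,
                 kept_idx = kept,
                 center = colMeans(X[, kept, drop = FALSE]),
                 scale = sds[kept]),
            class = "preprocess_model")
}

#' @rdname fit_preprocess
#' @param model A fitted `preprocess_model`.
#' @export
apply_preprocess <- function(model, X) {
  stopifnot(inherits(model, "preprocess_model"))
  Xk <- X[, model$kept_idx, drop = FALSE]
  scale(Xk, center = model$center, scale = model$scale)[, , drop = FALSE]
}

#' Synthetic minority over-sampling (SMOTE)
#'
#' Each synthetic sample is `x_i + u * (x_nn - x_i)` with `u ~ U(0,1)` and
#' `x_nn` one of the k nearest minority neighbours of a minority point
#' `x_i`, so all synthetics lie on segments between minority neighbours.
#'
#' @param X_minority Minority-class matrix (rows = samples).
#' @param n_synthetic Number of synthetic samples to generate.
#' @param k Neighbourhood size (default 5; reduced with a warning when the
#'   minority class is too small).
#' @param seed Integer seed.
#' @return Matrix of `n_synthetic` synthetic samples.
#' @export
smote <- function(X_minority, n_synthetic, k = 5, seed = 1) {
  stopifnot(is.matrix(X_minority))
  n <- nrow(X_minority)
  if (n < 2) stop("need at least 2 minority samples")
  if (n <= k) {
    warning(sprintf("minority size %d <= k = %d; using k = %d", n, k, n - 1))
    k <- n - 1
  }
  set.seed(derive_seed(seed, "smote"))
  d <- as.matrix(stats::dist(X_minority))
  diag(d) <- Inf
  nn <- matrix(apply(d, 1, function(r) order(r)[seq_len(k)]),
               nrow = n, ncol = k, byrow = TRUE)
  out <- matrix(0, n_synthetic, ncol(X_minority),
                dimnames = list(NULL, colnames(X_minority)))
  base_idx <- rep_len(seq_len(n), n_synthetic)
  for (s in seq_len(n_synthetic)) {
    i <- base_idx[s]
    j <- nn[i, sample.int(k, 1)]
    u <- runif(1)
    out[s, ] <- X_minority[i, ] + u * (X_minority[j, ] - X_minority[i, ])
  }
  out
}

#' Rebalance a two-class training set with SMOTE
#'
#' Oversamples the minority class to parity with the majority class.
#' Intended for the TRAINING partition only.
#'
#' @param X Feature matrix; `y` two-class factor.
#' @inheritParams smote
#' @return List with augmented `X`, `y`.
#' @export
smote_balance <- function(X, y, k = 5, seed = 1) {
  y <- as.factor(y)
  tab <- table(y)
  if (length(tab) != 2) stop("smote_balance expects exactly two classes")
  minority <- names(tab)[which.min(tab)]
  n_needed <- max(tab) - min(tab)
  if (n_needed == 0) return(list(X = X, y = y))
  syn <- smote(X[y == minority, , drop = FALSE], n_needed, k = k, seed = seed)
  list(X = rbind(X, syn),
       y = factor(c(as.character(y), rep(minority, n_needed)),
                  levels = levels(y)))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability
#' `P(score+ > score-) + 0.5 P(tie)` via mid-ranks, which equals the
#' trapezoidal integral of the ROC curve.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Logical, 0/1, or two-level factor; the positive class is
#'   `TRUE`, `1`, or the second factor level.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must be two-class")
    return(labels == levels(labels)[2])
  }
  u <- sort(unique(labels))
  if (length(u) != 2) stop("labels must be two-class")
  labels == u[2]
}

#' Stratified bootstrap confidence interval for the AUROC
#'
#' Percentile interval from `n_boot` bootstrap resamples drawn within each
#' class.
#'
#' @inheritParams auroc
#' @param n_boot Bootstrap replicates (default 2000).
#' @param level Coverage (default 0.95).
#' @param seed Integer seed.
#' @return Named vector `c(lower, upper)`.
#' @export
auroc_ci <- function(scores, labels, n_boot = 2000, level = 0.95, seed = 1) {
  pos <- as_positive(labels)
  ip <- which(pos); in_ <- which(!pos)
  set.seed(derive_seed(seed, "boot"))
  stats_ <- replicate(n_boot, {
    idx <- c(sample(ip, replace = TRUE), sample(in_, replace = TRUE))
    auroc(scores[idx], pos[idx])
  })
  a <- (1 - level) / 2
  stats::quantile(stats_, c(a, 1 - a), names = FALSE) |>
    stats::setNames(c("lower", "upper"))
}

#' Confusion matrix and its summary metrics
#'
#' `confusion_matrix` tabulates a 2x2 matrix from predicted and observed
#' classes; `confusion_metrics` returns accuracy, Cohen's kappa, and the
#' F1-score. F1 is `NA` (flagged) when no positives are predicted or
#' present; kappa is `NA` when the chance agreement is exactly 1.
#'
#' @param predicted,observed Two-class vectors (see [auroc()] for the
#'   positive-class convention).
#' @return `confusion_matrix`: list with tp, fp, fn, tn.
#' @export
confusion_matrix <- function(predicted, observed) {
  p <- as_positive(predicted); o <- as_positive(observed)
  stopifnot(length(p) == length(o))
  list(tp = sum(p & o), fp = sum(p & !o), fn = sum(!p & o), tn = sum(!p & !o))
}

#' @rdname confusion_matrix
#' @param cm List with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix")
  acc <- (tp + tn) / total
  f1 <- if ((tp + fp) == 0 || (tp + fn) == 0) NA_real_
        else 2 * tp / (2 * tp + fp + fn)
  p_yes <- ((tp + fp) / total) * ((tp + fn) / total)
  p_no <- ((fn + tn) / total) * ((fp + tn) / total)
  p_e <- p_yes + p_no
  kappa <- if (abs(1 - p_e) < 1e-12) NA_real_ else (acc - p_e) / (1 - p_e)
  list(accuracy = acc, kappa = kappa, f1 = f1)
}

#' Full test-set evaluation of continuous scores
#'
#' Binarizes the scores at `threshold` and reports AUROC (with bootstrap
#' CI), accuracy, kappa, and F1 — the four metrics used to compare
#' classifiers and clinical indices.
#'
#' @inheritParams auroc
#' @param threshold Binarization threshold on the score scale.
#' @param ci Logical; compute the bootstrap CI (default TRUE).
#' @param seed Integer seed for the bootstrap.
#' @return List with `auroc`, `auroc_ci`, `accuracy`, `kappa`, `f1`,
#'   `threshold`, `n`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5, ci = TRUE,
                            seed = 1) {
  cm <- confusion_matrix(scores >= threshold, labels)
  m <- confusion_metrics(cm)
  list(auroc = auroc(scores, labels),
       auroc_ci = if (ci) auroc_ci(scores, labels, seed = seed) else NULL,
       accuracy = m$accuracy, kappa = m$kappa, f1 = m$f1,
       threshold = threshold, n = length(scores))
}
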