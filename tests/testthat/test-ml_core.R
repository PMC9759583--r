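test_that("stratified split keeps per-class proportions within one sample", {
  lab <- rep(c("A", "B"), each = 10)
  sp <- stratified_split(lab, 0.8, seed = 1)
  expect_equal(sum(lab[sp$train] == "A"), 8)
  expect_equal(sum(lab[sp$test] == "B"), 2)
  expect_setequal(c(sp$train, sp$test), 1:20)
  sp2 <- stratified_split(lab, 0.8, seed = 1)
  expect_identical(sp, sp2)
  # study subgroup sizes: 38 + 128 at 80%
  lab2 <- rep(c("IRNF", "IRFL"), c(38, 128))
  sp3 <- stratified_split(lab2, 0.8, seed = 2)
  expect_lte(abs(sum(lab2[sp3$train] == "IRNF") - 30), 1)
  expect_lte(abs(sum(lab2[sp3$train] == "IRFL") - 102), 1)
  expect_error(stratified_split(c("A", "B", "B"), 0.8), "at least 2")
})

test_that("preprocessing drops zero-variance columns and z-scores with training stats", {
  set.seed(3)
  X <- cbind(const = rep(5, 20), a = rnorm(20), b = runif(20))
  pm <- fit_preprocess(X)
  expect_false("const" %in% pm$kept)
  Z <- apply_preprocess(pm, X)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-9)
  # a test value equal to the training mean maps to zero
  Xt <- rbind(c(5, pm$center["a"], pm$center["b"]))
  colnames(Xt) <- colnames(X)
  expect_lt(max(abs(apply_preprocess(pm, Xt))), 1e-12)
  expect_error(fit_preprocess(cbind(x = rep(1, 5))), "zero-variance")
})

test_that("smote synthetics lie on minority neighbour segments", {
  # degenerate: identical minority points reproduce themselves
  same <- matrix(1, 6, 2)
  expect_true(all(smote(same, 10, k = 2, seed = 1) == 1))
  # two points with k = 1: all synthetics on the segment
  two <- rbind(c(0, 0), c(1, 2))
  syn <- smote(two, 25, k = 1, seed = 2)
  tvec <- syn[, 1]
  expect_true(all(tvec >= 0 & tvec <= 1))
  expect_equal(syn[, 2], 2 * tvec, tolerance = 1e-12)
  expect_warning(smote(two, 5, k = 5, seed = 1), "k = 1")
})

test_that("smote_balance equalizes a two-class training set", {
  set.seed(9)
  X <- matrix(rnorm(60), 30, 2)
  y <- factor(rep(c("NF", "FL"), c(8, 22)), levels = c("NF", "FL"))
  sb <- smote_balance(X, y, seed = 4)
  expect_equal(unname(table(sb$y)["NF"]), unname(table(sb$y)["FL"]))
  expect_equal(nrow(sb$X), 44)
})

test_that("auroc equals pair counting, is rank-invariant, and complements", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  set.seed(77)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # ties likely
    lb <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    a <- auroc(sc, lb)
    expect_equal(a, oracle_auroc_pairs(sc, lb), tolerance = 1e-12)
    expect_equal(auroc(qlogis((sc + 0.5) / 2), lb), a, tolerance = 1e-12)
    if (!any(duplicated(sc)))
      expect_equal(auroc(-sc, lb), 1 - a, tolerance = 1e-12)
  }
})

test_that("confusion metrics match hand values and reconstruction", {
  perfect <- confusion_metrics(list(tp = 7, fp = 0, fn = 0, tn = 5))
  expect_equal(perfect, list(accuracy = 1, kappa = 1, f1 = 1))
  hand <- confusion_metrics(list(tp = 20, fp = 5, fn = 5, tn = 20))
  expect_equal(hand$accuracy, 0.8)
  expect_equal(hand$f1, 0.8)
  expect_equal(hand$kappa, 0.6)
  # chance agreement with matched marginals: kappa near zero
  chance <- confusion_metrics(list(tp = 25, fp = 25, fn = 25, tn = 25))
  expect_equal(chance$kappa, 0)
  # no predicted positives flags F1
  expect_true(is.na(confusion_metrics(list(tp = 0, fp = 0, fn = 3, tn = 7))$f1))
})

test_that("random forests separate blobs and rank the informative feature", {
  set.seed(15)
  n <- 100
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- factor(ifelse(X[, 1] > 0, "FL", "NF"), levels = c("NF", "FL"))
  X[, 1] <- X[, 1] + ifelse(y == "FL", 2, -2)
  fit <- train_rf(X, y, params = list(seed = 1))
  expect_equal(auroc(fit$predict_prob(X), y), 1)
  expect_equal(names(which.max(fit$importance)), "g1")
  expect_true(all(fit$importance >= 0))
  expect_error(train_rf(X, factor(rep("FL", n))), "two classes")
  # determinism under a fixed seed
  fit2 <- train_rf(X, y, params = list(seed = 1))
  expect_identical(fit$predict_prob(X), fit2$predict_prob(X))
})

test_that("repeated CV is perfect on separable data and seeded-deterministic", {
  set.seed(19)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("g", 1:3)))
  y <- factor(ifelse(X[, 1] > 0, "FL", "NF"), levels = c("NF", "FL"))
  X[, 1] <- X[, 1] + ifelse(y == "FL", 3, -3)
  cv <- repeated_cv_auroc(X, y, folds = 5, repeats = 2,
                          params = list(num_trees = 100), seed = 2)
  expect_equal(cv$mean_auroc, 1)
  expect_length(cv$fold_aurocs, 10)
  cv2 <- repeated_cv_auroc(X, y, folds = 5, repeats = 2,
                           params = list(num_trees = 100), seed = 2)
  expect_identical(cv, cv2)
})

test_that("feature curve ranks once and degenerates to plain CV", {
  set.seed(23)
  n <- 50
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("g1", "g2")))
  y <- factor(ifelse(X[, 1] + rnorm(n, 0, 0.5) > 0, "FL", "NF"),
              levels = c("NF", "FL"))
  curve <- sequential_feature_curve(X, y, ks = 2, folds = 5, repeats = 1,
                                    params = list(num_trees = 100), seed = 7)
  ref <- repeated_cv_auroc(X, y, folds = 5, repeats = 1,
                           params = list(num_trees = 100), seed = 7 + 2)
  expect_equal(curve$cv_auroc, ref$mean_auroc)
  expect_warning(
    sequential_feature_curve(X, y, ks = c(2, 5), folds = 5, repeats = 1,
                             params = list(num_trees = 50), seed = 1),
    "skipping")
  expect_length(attr(curve, "ranking"), 2)
})

test_that("evaluate_scores binds the four evaluation metrics together", {
  set.seed(27)
  y <- rep(c(TRUE, FALSE), each = 20)
  sc <- ifelse(y, 0.8, 0.2) + rnorm(40, 0, 0.05)
  ev <- evaluate_scores(sc, y, threshold = 0.5, seed = 3)
  expect_equal(ev$auroc, 1)
  expect_equal(ev$accuracy, 1)
  expect_true(ev$auroc_ci["lower"] <= ev$auroc)
  expect_equal(ev$n, 40)
})
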