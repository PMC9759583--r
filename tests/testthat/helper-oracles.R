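# Independent oracles used across the suite. These deliberately take a
# different computational route from the package implementations.

# AUROC by exhaustive concordant/tied pair counting.
oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + (p > q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}

# Faith's PD by brute force: an edge is counted iff the leaf set below it
# intersects the present set (root-connecting edges included).
oracle_faith_bruteforce <- function(present, tree) {
  desc_tips <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    below <- desc_tips(tree$edge[e, 2])
    if (length(intersect(below, present)) > 0)
      total <- total + tree$edge.length[e]
  }
  total
}

# Confusion-matrix metrics recomputed from reconstructed label vectors.
oracle_confusion_metrics <- function(tp, fp, fn, tn) {
  pred <- c(rep(TRUE, tp), rep(TRUE, fp), rep(FALSE, fn), rep(FALSE, tn))
  obs <- c(rep(TRUE, tp), rep(FALSE, fp), rep(TRUE, fn), rep(FALSE, tn))
  acc <- mean(pred == obs)
  # F1 undefined only when a marginal is empty; tp = 0 with both
  # marginals occupied is a defined F1 of 0
  f1 <- if (sum(pred) == 0 || sum(obs) == 0) NA_real_ else {
    prec <- sum(pred & obs) / sum(pred)
    rec <- sum(pred & obs) / sum(obs)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  n <- length(pred)
  pe <- (sum(pred) / n) * (sum(obs) / n) +
        (sum(!pred) / n) * (sum(!obs) / n)
  kappa <- if (abs(1 - pe) < 1e-12) NA_real_ else (acc - pe) / (1 - pe)
  list(accuracy = acc, kappa = kappa, f1 = f1)
}

# Brute-force k nearest neighbours among rows of X.
oracle_knn <- function(X, i, k) {
  d <- sqrt(colSums((t(X) - X[i, ])^2))
  d[i] <- Inf
  order(d)[seq_len(k)]
}

# Random point on the simplex.
random_simplex <- function(G) {
  x <- rexp(G)
  x / sum(x)
}

# Small two-arm insulin-resistant cohort in classifier-ready form.
make_ir_data <- function(seed, n_per_group = c(IRNF = 38, IRFL = 128), ...) {
  spec <- synthetic_spec(n_per_group = n_per_group, seed = seed, ...)
  ab <- generate_abundance(spec)
  rel <- relative_abundance(ab$table)
  list(X = rel$values,
       y = factor(ifelse(grepl("FL$", ab$labels), "FL", "NF"),
                  levels = c("NF", "FL")),
       truth = ab$truth)
}
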