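#' Shannon entropy of a relative-abundance vector
#'
#' `-sum(p * log(p, base))` with zero entries contributing zero. Base 2
#' by default (bits), matching common amplicon-workflow convention.
#'
#' @param p Non-negative vector summing to 1 within 1e-9.
#' @param log_base Logarithm base (default 2).
#' @return Entropy in `log_base` units.
#' @export
shannon <- function(p, log_base = 2) {
  if (any(p < 0)) stop("negative abundance entries")
  if (abs(sum(p) - 1) > 1e-9) stop("relative abundances must sum to 1")
  nz <- p[p > 0]
  -sum(nz * log(nz, base = log_base))
}

#' Pielou's evenness
#'
#' Shannon entropy divided by its maximum `log(S)` over the observed
#' (nonzero) taxa; the ratio is independent of the logarithm base and lies
#' in [0, 1], reaching 1 on the uniform composition.
#'
#' @param p Non-negative vector summing to 1 within 1e-9, with at least
#'   two nonzero taxa.
#' @return Evenness in [0, 1].
#' @export
pielou <- function(p) {
  if (any(p < 0)) stop("negative abundance entries")
  s_obs <- sum(p > 0)
  if (s_obs < 2) stop("evenness undefined with fewer than 2 observed taxa")
  shannon(p, log_base = 2) / log2(s_obs)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting the present
#' leaves to the root (root-connecting branches included).
#'
#' @param present_taxa Character vector of present leaf labels (nonempty).
#' @param tree A rooted `ape::phylo` with branch lengths.
#' @return PD in branch-length units.
#' @export
faith_pd <- function(present_taxa, tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(present_taxa) == 0) stop("present_taxa must be nonempty")
  unknown <- setdiff(present_taxa, tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown taxon: ", paste(unknown, collapse = ", "))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  # parent lookup over the edge matrix, then union the root paths
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  on_path <- logical(max(tree$edge))
  for (tip in match(present_taxa, tree$tip.label)) {
    v <- tip
    while (v != root && !on_path[v]) {
      on_path[v] <- TRUE
      v <- parent[v]
    }
  }
  sum(elen[on_path])
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i,j) = sum |x_i - x_j| / sum (x_i + x_j)` over genera, on closed
#' relative abundances; values lie in [0, 1].
#'
#' @param table An `abundance_table` in relative mode (convert counts with
#'   [relative_abundance()] first).
#' @return A symmetric `dist`-like matrix with zero diagonal and the
#'   sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "relative")
    stop("bray_curtis expects relative mode; use relative_abundance() first")
  x <- table$values
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(abs(x[i, ] - x[j, ]))
      den <- sum(x[i, ] + x[j, ])
      d[i, j] <- d[j, i] <- if (den == 0) 0 else num / den
    }
  }
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-0.5 * D^2`, eigendecomposes, and returns the top-k
#' coordinates scaled by the square root of their (positive) eigenvalues.
#' Axis signs are fixed so the largest-magnitude loading on each axis is
#' positive, making ordinations reproducible.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @param k Number of axes (1 <= k < n).
#' @return List with `coordinates` (n x k), `eigenvalues` (descending, all
#'   n), and `proportion_explained` (relative to the positive eigenvalues).
#' @export
pcoa <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  if (max(abs(D - t(D))) > 1e-8 || any(diag(D) != 0))
    stop("D must be symmetric with zero diagonal")
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- e$values
  coords <- matrix(0, n, k, dimnames = list(rownames(D), paste0("PCo", 1:k)))
  for (a in seq_len(k)) {
    if (lam[a] > 1e-12) {
      v <- e$vectors[, a] * sqrt(lam[a])
      if (v[which.max(abs(v))] < 0) v <- -v
      coords[, a] <- v
    }
  }
  pos <- sum(lam[lam > 0])
  list(coordinates = coords, eigenvalues = lam,
       proportion_explained = ifelse(lam > 0, lam / pos, 0)[seq_len(k)])
}

#' Rank-based group comparison
#'
#' Two groups: two-sided Wilcoxon rank-sum; more: Kruskal-Wallis. The
#' distribution-free tests the study used for diversity and abundance
#' contrasts.
#'
#' @param values Numeric vector.
#' @param labels Group labels aligned with `values` (>= 2 groups, >= 2
#'   values per group).
#' @return List with `statistic`, `p_value`, `method`.
#' @export
group_compare <- function(values, labels) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("need at least two values per group")
  if (length(unique(values)) == 1) {
    warning("constant values across groups; p = 1")
    return(list(statistic = NA_real_, p_value = 1, method = "degenerate"))
  }
  if (length(tab) == 2) {
    grp <- split(values, labels)
    ht <- suppressWarnings(stats::wilcox.test(grp[[1]], grp[[2]],
                                              alternative = "two.sided"))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "wilcoxon_rank_sum")
  } else {
    ht <- stats::kruskal.test(values, labels)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "kruskal_wallis")
  }
}

#' Per-sample alpha diversity report with group tests
#'
#' Computes Shannon entropy, Pielou's evenness and (when a tree is given)
#' Faith's PD for every sample, and rank-tests each index across groups.
#'
#' @param table An `abundance_table` (counts are closed internally).
#' @param groups Group label per sample.
#' @param tree Optional rooted phylogeny over the genus ids.
#' @return List with `per_sample` (data frame) and `tests` (data frame of
#'   index, statistic, p_value, method).
#' @export
alpha_diversity_report <- function(table, groups, tree = NULL) {
  rel <- relative_abundance(table)
  n <- nrow(rel$values)
  stopifnot(length(groups) == n)
  sh <- apply(rel$values, 1, shannon)
  pe <- apply(rel$values, 1, pielou)
  per <- data.frame(sample_id = rownames(rel$values), group = groups,
                    shannon = sh, pielou = pe, stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    per$faith_pd <- apply(rel$values, 1, function(r)
      faith_pd(colnames(rel$values)[r > 0], tree))
  }
  idx <- setdiff(names(per), c("sample_id", "group"))
  tests <- do.call(rbind, lapply(idx, function(v) {
    gt <- group_compare(per[[v]], groups)
    data.frame(index = v, statistic = gt$statistic, p_value = gt$p_value,
               method = gt$method, stringsAsFactors = FALSE)
  }))
  list(per_sample = per, tests = tests)
}
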