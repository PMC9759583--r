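test_that("shannon entropy matches hand values and vegan", {
  expect_equal(shannon(c(1, 0, 0)), 0)
  expect_equal(shannon(rep(1 / 64, 64)), 6)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon(c(-0.1, 1.1)), "negative")
  skip_if_not_installed("vegan")
  set.seed(101)
  for (i in 1:50) {
    p <- random_simplex(sample(5:87, 1))
    expect_equal(shannon(p), vegan::diversity(p, "shannon") / log(2),
                 tolerance = 1e-9)
  }
})

test_that("shannon is maximal only on the uniform composition", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_simplex(87)
    expect_lt(shannon(p), log2(87))
  }
  expect_equal(shannon(rep(1 / 87, 87)), log2(87))
})

test_that("pielou evenness is the base-free entropy ratio", {
  expect_equal(pielou(rep(0.25, 4)), 1)
  expect_equal(pielou(c(0.5, 0.25, 0.25)), 1.5 / log2(3))
  expect_error(pielou(c(1, 0, 0)), "fewer than 2")
  # near-degenerate composition tends to zero evenness
  eps <- 1e-9
  expect_lt(pielou(c(1 - eps, rep(eps / 9, 9))), 1e-6)
})

test_that("faith PD matches star/total cases and brute force", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_equal(faith_pd(c("a", "b", "c"), star), 3)
  tr <- generate_tree(8, seed = 21)
  expect_equal(faith_pd(tr$tip.label, tr), sum(tr$edge.length))
  expect_error(faith_pd("nope", tr), "nope")
  set.seed(13)
  for (i in 1:20) {
    k <- sample(1:8, 1)
    present <- sample(tr$tip.label, k)
    expect_equal(faith_pd(present, tr),
                 oracle_faith_bruteforce(present, tr), tolerance = 1e-9)
  }
})

test_that("faith PD agrees with picante and grows monotonically", {
  skip_if_not_installed("picante")
  tr <- generate_tree(30, seed = 33)
  set.seed(14)
  for (i in 1:10) {
    present <- sample(tr$tip.label, sample(2:29, 1))
    comm <- matrix(as.integer(tr$tip.label %in% present), 1,
                   dimnames = list("s1", tr$tip.label))
    expect_equal(faith_pd(present, tr),
                 picante::pd(comm, tr, include.root = TRUE)$PD,
                 tolerance = 1e-9)
    extra <- sample(setdiff(tr$tip.label, present), 1)
    expect_gte(faith_pd(c(present, extra), tr), faith_pd(present, tr))
  }
})

test_that("bray-curtis matches hand values and vegan", {
  m <- matrix(c(0.5, 0.5, 0, 0.5, 0, 0.5, 0.5, 0.5, 0), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("g1", "g2", "g3")))
  tab <- abundance_table(m, mode = "relative")
  d <- bray_curtis(tab)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)
  disj <- abundance_table(
    matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("g1", "g2"))),
    mode = "relative")
  expect_equal(bray_curtis(disj)["a", "b"], 1)
  skip_if_not_installed("vegan")
  set.seed(31)
  x <- t(replicate(6, random_simplex(20)))
  dimnames(x) <- list(paste0("s", 1:6), paste0("g", 1:20))
  tab <- abundance_table(x / rowSums(x), mode = "relative")
  expect_equal(bray_curtis(tab),
               as.matrix(vegan::vegdist(tab$values, "bray")),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("bray-curtis satisfies identity and symmetry and refuses counts", {
  set.seed(41)
  x <- t(replicate(5, random_simplex(10)))
  dimnames(x) <- list(paste0("s", 1:5), paste0("g", 1:10))
  tab <- abundance_table(x / rowSums(x), mode = "relative")
  d <- bray_curtis(tab)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  cnt <- abundance_table(matrix(1:4, 2, dimnames = list(c("a", "b"),
                                                        c("g1", "g2"))),
                         mode = "counts")
  expect_error(bray_curtis(cnt), "relative")
})

test_that("pcoa recovers euclidean configurations and matches cmdscale", {
  two <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  co <- pcoa(two, k = 1)
  expect_equal(unname(sort(co$coordinates[, 1])), c(-1, 1))
  set.seed(55)
  pts <- cbind(runif(7), runif(7))
  D <- as.matrix(dist(pts))
  co <- pcoa(D, k = 2)
  expect_equal(as.matrix(dist(co$coordinates)), D,
               tolerance = 1e-9, ignore_attr = TRUE)
  ref <- stats::cmdscale(D, k = 2, eig = TRUE)
  expect_equal(co$eigenvalues[1:2], ref$eig[1:2], tolerance = 1e-9)
  for (a in 1:2) {
    v <- co$coordinates[, a]; w <- ref$points[, a]
    expect_lt(min(sqrt(sum((v - w)^2)), sqrt(sum((v + w)^2))), 1e-8)
  }
  expect_error(pcoa(D, k = 7), "k must")
})

test_that("group comparison dispatches to the right rank test", {
  set.seed(61)
  a <- rnorm(10); b <- rnorm(10) + 2
  gc2 <- group_compare(c(a, b), rep(c("A", "B"), each = 10))
  ref <- stats::wilcox.test(a, b)
  expect_equal(gc2$p_value, ref$p.value)
  expect_equal(gc2$method, "wilcoxon_rank_sum")
  v3 <- rnorm(30)
  g3 <- rep(c("A", "B", "C"), each = 10)
  gc3 <- group_compare(v3, g3)
  expect_equal(gc3$p_value, stats::kruskal.test(v3, factor(g3))$p.value)
  expect_warning(gcc <- group_compare(rep(1, 10), rep(c("A", "B"), 5)),
                 "constant")
  expect_equal(gcc$p_value, 1)
  expect_error(group_compare(1:4, c("A", "A", "A", "B")), "two values")
})

test_that("fully separated groups attain the minimal exact two-sided p", {
  a <- 1:10; b <- 21:30
  gc <- group_compare(c(a, b), rep(c("A", "B"), each = 10))
  # exact enumeration: 2 / C(20,10) for the two extreme orderings
  expect_equal(gc$p_value, 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("alpha diversity report tests each index across groups", {
  spec <- synthetic_spec(n_per_group = c(IRNF = 10, IRFL = 12), seed = 8)
  co <- generate_cohort(spec)
  rep_ <- alpha_diversity_report(co$abundance,
                                 ifelse(grepl("FL$", co$labels), "FL", "NF"),
                                 tree = co$tree)
  expect_setequal(rep_$tests$index, c("shannon", "pielou", "faith_pd"))
  expect_true(all(rep_$tests$p_value > 0 & rep_$tests$p_value <= 1))
  expect_equal(nrow(rep_$per_sample), 22)
})
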