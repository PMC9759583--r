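test_that("the penalized fitness score follows its closed form", {
  expect_identical(fitness_score(c(1, 1, 1), x = 10, b = 10, W = 10), 100)
  expect_equal(fitness_score(c(0.8, 0.9, 1.0), x = 12, b = 10, W = 10), 70)
  expect_equal(fitness_score(c(0.5, 0.5, 0.5), x = 10, b = 10, W = 10), 50)
  set.seed(2)
  for (i in 1:25) {
    S <- runif(3); x <- sample(0:87, 1); b <- sample(6:10, 1)
    sc <- fitness_score(S, x, b, W = 10)
    expect_lte(sc, 100)
    # penalty depends on x only through |x - b|
    expect_equal(sc, fitness_score(S, 2 * b - x, b, W = 10))
  }
  expect_equal(fitness_score(c(1, 1, 1), x = 15, b = 10, W = 0), 100)
})

test_that("fitness evaluation wires CV AUROCs into the score", {
  set.seed(5)
  n <- 45
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("g", 1:6)))
  y <- factor(ifelse(X[, 2] > 0, "FL", "NF"), levels = c("NF", "FL"))
  X[, 2] <- X[, 2] + ifelse(y == "FL", 4, -4)
  spec <- fitness_spec(M = 3, W = 10, b = 1, num_trees = 100, seed = 3)
  ev <- ga_fitness(c(0, 1, 0, 0, 0, 0), X, y, spec)
  expect_equal(ev$x, 1)
  expect_length(ev$S, 3)
  expect_equal(ev$score, 100 * mean(ev$S))
  expect_equal(ev$S, c(1, 1, 1))  # perfectly separable single feature
  empty <- ga_fitness(rep(0, 6), X, y, spec)
  expect_identical(empty$score, -Inf)
  expect_equal(empty$x, 0)
})

test_that("initial populations are seeded Bernoulli masks centred on b", {
  cfg <- ga_config(population_size = 300, seed = 42)
  p1 <- init_population(cfg, G = 87, b = 10)
  p2 <- init_population(cfg, G = 87, b = 10)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(300, 87))
  mean_pc <- mean(rowSums(p1))
  # binomial: mean 10, SE of the population mean = sqrt(10*77/87)/sqrt(300)
  expect_lt(abs(mean_pc - 10), 3 * sqrt(10 * (1 - 10 / 87)) / sqrt(300))
  expect_warning(init_population(ga_config(seed = 1, init_p = 0), G = 10),
                 "all-zero")
})

test_that("evolution keeps the elite and respects operator boundaries", {
  set.seed(11)
  pop <- matrix(as.integer(runif(20 * 8) < 0.5), 20, 8)
  fits <- rowSums(pop)  # deterministic surrogate
  # no variation + maximal tournament: one generation of copies of the best
  cfg0 <- ga_config(population_size = 20, crossover_rate = 0,
                    mutation_rate = 0, tournament_size = 20, seed = 1)
  nxt <- evolve(pop, fits, cfg0)
  best <- pop[which.max(fits), ]
  expect_true(all(apply(nxt, 1, function(r) all(r == best))))
  # mutation 1 flips every bit of every non-elite child
  cfg1 <- ga_config(population_size = 4, crossover_rate = 0,
                    mutation_rate = 1, tournament_size = 4, seed = 1)
  pop4 <- matrix(rep(c(1L, 0L, 1L, 0L), 4), 4, 4, byrow = TRUE)
  nxt1 <- evolve(pop4, rep(1, 4), cfg1)
  expect_equal(nxt1[1, ], pop4[1, ])           # elite untouched
  for (r in 2:4) expect_equal(nxt1[r, ], 1L - pop4[1, ])
})

test_that("the GA maximizes a toy popcount objective to the known optimum", {
  res <- run_ga(G = 8,
                ga = ga_config(population_size = 20, generations = 30,
                               mutation_rate = 0.05, seed = 13),
                fit = fitness_spec(b = 8, W = 0),
                fitness_fun = function(mask) sum(mask))
  expect_equal(res$best_mask, rep(1L, 8))
  expect_equal(res$best_score, 8)
  expect_true(all(diff(res$trajectory) >= 0))
  expect_lte(res$n_evaluations, 2^8)
})

test_that("GA runs are deterministic under a fixed seed", {
  surrogate <- function(mask) sum(mask * (1:10)) - 5 * abs(sum(mask) - 3)
  ga <- ga_config(population_size = 15, generations = 10, seed = 99)
  r1 <- run_ga(G = 10, ga = ga, fit = fitness_spec(b = 3),
               fitness_fun = surrogate)
  r2 <- run_ga(G = 10, ga = ga, fit = fitness_spec(b = 3),
               fitness_fun = surrogate)
  expect_identical(r1$best_mask, r2$best_mask)
  expect_identical(r1$trajectory, r2$trajectory)
})

test_that("a planted separating genus is selected under the size penalty", {
  set.seed(17)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("g", 1:8)))
  y <- factor(ifelse(X[, 3] > 0, "FL", "NF"), levels = c("NF", "FL"))
  X[, 3] <- X[, 3] + ifelse(y == "FL", 4, -4)
  res <- run_ga(X, y,
                ga = ga_config(population_size = 20, generations = 8,
                               seed = 5),
                fit = fitness_spec(M = 3, W = 10, b = 1, num_trees = 100,
                                   seed = 5))
  expect_equal(which(res$best_mask == 1), 3)
  expect_gt(res$best_score, 90)
  expect_true(all(diff(res$trajectory) >= 0))
})

test_that("select_b sweeps the subset-size grid and flags a winner", {
  set.seed(21)
  n <- 50
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("g", 1:6)))
  y <- factor(ifelse(X[, 1] > 0, "FL", "NF"), levels = c("NF", "FL"))
  X[, 1] <- X[, 1] + ifelse(y == "FL", 3, -3)
  ga <- ga_config(population_size = 12, generations = 4, seed = 7)
  fit <- fitness_spec(M = 3, W = 10, num_trees = 50, seed = 7)
  tab <- select_b(X, y, ga = ga, fit = fit, b_grid = c(1, 2))
  expect_equal(tab$b, c(1, 2))
  expect_equal(sum(tab$best), 1)
  single <- run_ga(X, y, ga = ga,
                   fit = fitness_spec(M = 3, W = 10, b = 1, num_trees = 50,
                                      seed = 7))
  expect_equal(tab$score[1], single$best_score)
  masks <- attr(tab, "masks")
  expect_equal(sum(masks[["1"]]), tab$popcount[1])
})

test_that("refit on the winning mask evaluates once on held-out data", {
  set.seed(25)
  n <- 80
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- factor(ifelse(X[, 2] > 0, "FL", "NF"), levels = c("NF", "FL"))
  X[, 2] <- X[, 2] + ifelse(y == "FL", 3, -3)
  sp <- stratified_split(y, 0.8, seed = 1)
  ev <- refit_and_evaluate(c(0, 1, 0, 0, 0),
                           X[sp$train, ], y[sp$train],
                           X[sp$test, ], y[sp$test],
                           params = list(num_trees = 100, seed = 1))
  expect_equal(ev$auroc, 1)
  expect_equal(ev$features, "g2")
  expect_error(refit_and_evaluate(rep(0, 5), X, y, X, y), "empty mask")
})
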