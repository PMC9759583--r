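#' Penalized cross-validated-AUROC fitness score
#'
#' The scalar objective the genetic algorithm maximizes:
#' `100 * mean(S) - W * |x - b|`, where `S` holds the per-fold AUROCs of
#' the classifier restricted to the selected genera, `x` is the number of
#' selected genera, `b` the target subset size, and `W` the penalty
#' weight. The analytic maximum is 100, attained only when every fold
#' AUROC is 1 and `x = b`.
#'
#' @param S Per-fold AUROC values in [0, 1].
#' @param x Selected-genus count.
#' @param b Target subset size.
#' @param W Penalty weight (>= 0).
#' @return The fitness score (<= 100).
#' @export
fitness_score <- function(S, x, b, W = 10) {
  stopifnot(all(S >= 0 & S <= 1), W >= 0, b >= 1)
  100 * mean(S) - W * abs(x - b)
}

#' Fitness-evaluation settings
#'
#' @param M Cross-validation fold count inside the fitness (default 3).
#' @param W Penalty weight (default 10).
#' @param b Target subset size (default 10; the study searched 6..10).
#' @param num_trees Trees per random forest inside the fitness CV
#'   (default 500).
#' @param seed Seed fixing the fold assignment, shared across all masks in
#'   a run so fitness differences reflect masks, not fold noise.
#' @return A `fitness_spec`.
#' @export
fitness_spec <- function(M = 3, W = 10, b = 10, num_trees = 500, seed = 1) {
  stopifnot(M >= 2, W >= 0, b >= 1)
  structure(list(M = M, W = W, b = b, num_trees = num_trees, seed = seed),
            class = "fitness_spec")
}

#' Evaluate the fitness of one feature mask
#'
#' Restricts the data to the mask's selected genera, runs an M-fold
#' stratified CV of the random forest, and scores the per-fold AUROCs with
#' [fitness_score()]. The empty mask scores `-Inf` (never selected).
#'
#' @param mask Binary vector over genera (1 = selected).
#' @param X Feature matrix; `y` two-class labels.
#' @param spec A `fitness_spec`.
#' @param fold Optional precomputed fold assignment (internal reuse).
#' @return List with `S` (per-fold AUROCs), `x` (popcount), `score`.
#' @export
ga_fitness <- function(mask, X, y, spec = fitness_spec(), fold = NULL) {
  stopifnot(length(mask) == ncol(X))
  x <- sum(mask != 0)
  if (x == 0) return(list(S = rep(NA_real_, spec$M), x = 0, score = -Inf))
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("y must be two-class")
  if (is.null(fold)) fold <- cv_folds(y, spec$M, seed = spec$seed)
  Xm <- X[, which(mask != 0), drop = FALSE]
  S <- numeric(spec$M)
  for (f in seq_len(spec$M)) {
    tr <- fold != f; te <- fold == f
    fit <- train_rf(Xm[tr, , drop = FALSE], y[tr],
                    params = list(num_trees = spec$num_trees,
                                  seed = spec$seed * 101 + f))
    S[f] <- auroc(fit$predict_prob(Xm[te, , drop = FALSE]), y[te])
  }
  list(S = S, x = x, score = fitness_score(S, x, spec$b, spec$W))
}

#' Genetic-algorithm settings
#'
#' Defaults follow the study's schedule: population 300, crossover rate
#' 0.8, per-bit mutation rate 0.003, 100 generations, single-individual
#' elitism. Selection is tournament (size 3) by default; `"roulette"`
#' selection and `"one_point"` crossover are available.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param crossover_rate Probability a selected pair is recombined.
#' @param mutation_rate Per-bit flip probability.
#' @param generations Number of generations.
#' @param elitism Number of top individuals copied unchanged (default 1).
#' @param tournament_size Tournament size for selection.
#' @param selection `"tournament"` or `"roulette"`.
#' @param crossover `"uniform"` or `"one_point"`.
#' @param init_p Initial per-bit inclusion probability (default `b/G`, so
#'   the size penalty starts near zero).
#' @param seed Integer seed.
#' @return A `ga_config`.
#' @export
ga_config <- function(population_size = 300, crossover_rate = 0.8,
                      mutation_rate = 0.003, generations = 100,
                      elitism = 1, tournament_size = 3,
                      selection = c("tournament", "roulette"),
                      crossover = c("uniform", "one_point"),
                      init_p = NULL, seed = 1) {
  stopifnot(population_size >= 2,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            generations >= 1, elitism >= 0)
  structure(list(population_size = population_size,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 generations = generations, elitism = elitism,
                 tournament_size = tournament_size,
                 selection = match.arg(selection),
                 crossover = match.arg(crossover),
                 init_p = init_p, seed = seed),
            class = "ga_config")
}

#' Random initial population of feature masks
#'
#' Bits are i.i.d. Bernoulli(`init_p`); the default `init_p = b/G` makes
#' the expected popcount equal the target subset size.
#'
#' @param config A `ga_config`.
#' @param G Number of genera (mask length).
#' @param b Target subset size used for the default `init_p`.
#' @return 0/1 matrix, `population_size` x `G`.
#' @export
init_population <- function(config, G, b = 10) {
  stopifnot(G >= 1)
  p <- config$init_p %||% (b / G)
  if (p <= 0) warning("init_p <= 0 produces all-zero masks")
  set.seed(derive_seed(config$seed, "ga"))
  matrix(as.integer(runif(config$population_size * G) < p),
         nrow = config$population_size, ncol = G)
}

select_parent <- function(pop, fitnesses, config) {
  n <- nrow(pop)
  if (config$selection == "tournament") {
    cand <- sample.int(n, min(config$tournament_size, n))
    cand[which.max(fitnesses[cand])]
  } else {
    w <- fitnesses - min(fitnesses[is.finite(fitnesses)], 0) + 1e-9
    w[!is.finite(w) | w < 0] <- 0
    sample.int(n, 1, prob = w)
  }
}

#' One generation of the genetic algorithm
#'
#' The elite (highest fitness, ties broken by lowest index) is copied
#' unchanged; the remaining slots are filled by selection, pairwise
#' crossover with probability `crossover_rate`, and per-bit mutation.
#' RNG state is taken as-is: [run_ga()] seeds the stream once per run.
#'
#' @param population 0/1 matrix of masks.
#' @param fitnesses Fitness per row of `population`.
#' @param config A `ga_config`.
#' @return The next population (same dimensions).
#' @export
evolve <- function(population, fitnesses, config) {
  n <- nrow(population); G <- ncol(population)
  stopifnot(length(fitnesses) == n)
  nxt <- matrix(0L, n, G)
  n_elite <- min(config$elitism, n)
  if (n_elite > 0) {
    ord <- order(-fitnesses, seq_len(n))
    nxt[seq_len(n_elite), ] <- population[ord[seq_len(n_elite)], , drop = FALSE]
  }
  i <- n_elite
  while (i < n) {
    p1 <- population[select_parent(population, fitnesses, config), ]
    p2 <- population[select_parent(population, fitnesses, config), ]
    if (runif(1) < config$crossover_rate) {
      if (config$crossover == "uniform") {
        swap <- runif(G) < 0.5
        tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
      } else {
        cut <- sample.int(G - 1, 1)
        tmp <- p1[1:cut]; p1[1:cut] <- p2[1:cut]; p2[1:cut] <- tmp
      }
    }
    for (child in list(p1, p2)) {
      if (i >= n) break
      flip <- runif(G) < config$mutation_rate
      child[flip] <- 1L - child[flip]
      i <- i + 1
      nxt[i, ] <- child
    }
  }
  nxt
}

#' Run the genetic algorithm feature search
#'
#' Evolves a population of binary genus masks, evaluating each distinct
#' mask once (memoized) with [ga_fitness()] or a caller-supplied fitness
#' function, and returns the best-ever individual together with the
#' per-generation best-fitness trajectory (non-decreasing under elitism).
#'
#' @param X Feature matrix; `y` two-class labels. Ignored when
#'   `fitness_fun` is supplied.
#' @param ga A `ga_config`.
#' @param fit A `fitness_spec`.
#' @param fitness_fun Optional `function(mask) -> numeric` surrogate
#'   fitness (used for testing and custom objectives).
#' @param G Mask length when `fitness_fun` is given without `X`.
#' @return List with `best_mask`, `best_score`, `best_eval` (full
#'   [ga_fitness()] result when applicable), `trajectory`
#'   (per-generation best-ever fitness), `n_evaluations` (distinct masks
#'   evaluated).
#' @export
run_ga <- function(X = NULL, y = NULL, ga = ga_config(),
                   fit = fitness_spec(), fitness_fun = NULL, G = NULL) {
  if (is.null(fitness_fun)) {
    stopifnot(!is.null(X), !is.null(y))
    G <- ncol(X)
    y <- as.factor(y)
    # fold assignment is re-drawn each generation but shared by every
    # individual within it: fitness differences reflect masks, and no
    # single fold split can be adaptively overfit across generations
    gen_fold <- NULL
    gen_tag <- 0L
    evals <- new.env(hash = TRUE, parent = emptyenv())
    fitness_fun <- function(mask) {
      key <- paste0(gen_tag, ":", paste(as.integer(mask), collapse = ""))
      got <- get0(key, envir = evals)
      if (!is.null(got)) return(got)
      val <- ga_fitness(mask, X, y, fit, fold = gen_fold)
      assign(key, val, envir = evals)
      val
    }
    score_of <- function(v) v$score
  } else {
    stopifnot(!is.null(G) || !is.null(X))
    if (is.null(G)) G <- ncol(X)
    evals <- new.env(hash = TRUE, parent = emptyenv())
    raw_fun <- fitness_fun
    fitness_fun <- function(mask) {
      key <- paste(as.integer(mask), collapse = "")
      got <- get0(key, envir = evals)
      if (!is.null(got)) return(got)
      val <- raw_fun(mask)
      assign(key, val, envir = evals)
      val
    }
    score_of <- function(v) if (is.list(v)) v$score else v
  }

  pop <- init_population(ga, G, b = fit$b)
  set.seed(derive_seed(ga$seed, "ga") + 1L)
  best_score <- -Inf; best_mask <- NULL; best_eval <- NULL
  trajectory <- numeric(ga$generations)
  real_fitness <- exists("gen_fold", inherits = FALSE)
  for (gen in seq_len(ga$generations)) {
    if (real_fitness) {
      gen_tag <- gen
      gen_fold <- cv_folds(y, fit$M,
                           seed = (fit$seed %% 65536) * 16384 + gen)
    }
    res <- apply(pop, 1, fitness_fun)
    scores <- vapply(res, score_of, numeric(1))
    gi <- which.max(scores)
    if (scores[gi] > best_score) {
      best_score <- scores[gi]
      best_mask <- pop[gi, ]
      best_eval <- res[[gi]]
    }
    trajectory[gen] <- best_score
    if (gen < ga$generations) pop <- evolve(pop, scores, ga)
  }
  list(best_mask = best_mask, best_score = best_score,
       best_eval = best_eval, trajectory = trajectory,
       n_evaluations = length(ls(evals)))
}

#' Sweep the target subset size b
#'
#' Runs the GA once per value of `b_grid` (the study searched 6..10),
#' reporting each winner; when a held-out test set is supplied, each
#' winning mask is refit on the full training data and its test AUROC
#' reported, and the row with the best test AUROC is flagged.
#'
#' @inheritParams run_ga
#' @param b_grid Candidate subset sizes.
#' @param X_test,y_test Optional held-out test set.
#' @param refit_params Engine parameters for the final refits.
#' @return Data frame with one row per b (`b`, `score`, `popcount`,
#'   `test_auroc`, `best`); winning masks attached as attribute `"masks"`.
#' @export
select_b <- function(X, y, ga = ga_config(), fit = fitness_spec(),
                     b_grid = 6:10, X_test = NULL, y_test = NULL,
                     refit_params = list()) {
  stopifnot(length(b_grid) >= 1)
  masks <- list()
  rows <- lapply(b_grid, function(b) {
    fb <- fit; fb$b <- b
    r <- run_ga(X, y, ga = ga, fit = fb)
    masks[[as.character(b)]] <<- r$best_mask
    test_auc <- NA_real_
    if (!is.null(X_test)) {
      ev <- refit_and_evaluate(r$best_mask, X, y, X_test, y_test,
                               params = refit_params, ci = FALSE)
      test_auc <- ev$auroc
    }
    data.frame(b = b, score = r$best_score, popcount = sum(r$best_mask),
               test_auroc = test_auc)
  })
  out <- do.call(rbind, rows)
  out$best <- FALSE
  if (!all(is.na(out$test_auroc)))
    out$best[which.max(out$test_auroc)] <- TRUE
  else out$best[which.max(out$score)] <- TRUE
  attr(out, "masks") <- masks
  out
}

#' Refit the winning mask and evaluate once on held-out data
#'
#' After the GA search, a fresh classifier is fit on the full training
#' partition restricted to the selected genera and evaluated a single
#' time on the held-out test partition.
#'
#' @param mask Binary mask over the columns of `X_train`.
#' @param X_train,y_train Training partition.
#' @param X_test,y_test Held-out test partition.
#' @param params Engine parameters (default 500-tree random forest).
#' @param threshold Probability threshold for the confusion metrics.
#' @param ci Logical; bootstrap CI for the AUROC.
#' @return [evaluate_scores()] output plus `features` (selected genus ids)
#'   and `model`.
#' @export
refit_and_evaluate <- function(mask, X_train, y_train, X_test, y_test,
                               params = list(), threshold = 0.5, ci = TRUE) {
  sel <- which(mask != 0)
  if (length(sel) == 0) stop("empty mask cannot be refit")
  fit <- train_rf(X_train[, sel, drop = FALSE], y_train, params = params)
  scores <- fit$predict_prob(X_test[, sel, drop = FALSE])
  ev <- evaluate_scores(scores, y_test, threshold = threshold, ci = ci,
                        seed = params$seed %||% 1)
  ev$features <- colnames(X_train)[sel]
  ev$model <- fit
  ev
}
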