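#' Configuration for an end-to-end pipeline run
#'
#' One object drives the whole study replica: simulate (or load) a cohort,
#' depth-QC, subgroup stratification, diversity report, Gini feature
#' curve, GA feature selection with final refit, clinical-index
#' comparison. A single global seed fans out to per-stage streams.
#'
#' @param out_dir Output directory.
#' @param spec A `synthetic_spec` (used unless `abundance_path` /
#'   `metadata_path` point at files to load).
#' @param abundance_path,metadata_path,tree_path Optional input files.
#' @param group Which stratum to classify: `"IR"`, `"IS"`, or `"ALL"`.
#' @param min_depth QC depth cutoff (default 5000).
#' @param cutoffs Sex-specific HOMA-IR cutoffs.
#' @param train_fraction Train split (default 0.8).
#' @param cv_folds,cv_repeats Feature-curve CV geometry.
#' @param feature_ks Feature counts for the sequential curve.
#' @param ga A `ga_config`; `fit` a `fitness_spec`.
#' @param fit A `fitness_spec`.
#' @param rf_params Engine parameters for refits and curves.
#' @param use_smote Rebalance the training partition with SMOTE before the
#'   final refit.
#' @param thresholds Index binarization cutoffs.
#' @param seed Global seed.
#' @return A `run_config`.
#' @export
run_config <- function(out_dir,
                       spec = synthetic_spec(),
                       abundance_path = NULL, metadata_path = NULL,
                       tree_path = NULL,
                       group = c("IR", "IS", "ALL"),
                       min_depth = 5000,
                       cutoffs = c(M = 1.8, F = 2.2),
                       train_fraction = 0.8,
                       cv_folds = 10, cv_repeats = 3,
                       feature_ks = c(2, 4, 8, 12, 16, 24, 32),
                       ga = ga_config(),
                       fit = fitness_spec(),
                       rf_params = list(),
                       use_smote = TRUE,
                       thresholds = index_thresholds(),
                       seed = 1) {
  structure(list(out_dir = out_dir, spec = spec,
                 abundance_path = abundance_path,
                 metadata_path = metadata_path, tree_path = tree_path,
                 group = match.arg(group), min_depth = min_depth,
                 cutoffs = cutoffs, train_fraction = train_fraction,
                 cv_folds = cv_folds, cv_repeats = cv_repeats,
                 feature_ks = feature_ks, ga = ga, fit = fit,
                 rf_params = rf_params, use_smote = use_smote,
                 thresholds = thresholds, seed = seed),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes simulate/load -> depth QC -> HOMA-IR stratification ->
#' diversity report -> Gini sequential feature curve -> GA feature
#' selection -> final refit and held-out evaluation -> clinical-index
#' comparison, writing every artifact plus a manifest (config echo, stage
#' seeds, file hashes) into `config$out_dir`.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stage_seeds <- list(simulate = derive_seed(seed, "pipeline"),
                      split = derive_seed(seed, "split"),
                      ga = derive_seed(seed, "ga"),
                      smote = derive_seed(seed, "smote"))

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$abundance_path)) {
    table <- read_abundance(config$abundance_path, mode = "counts")
    clinical <- utils::read.csv(config$metadata_path,
                                stringsAsFactors = FALSE)
    tree <- if (!is.null(config$tree_path)) ape::read.tree(config$tree_path)
  } else {
    spec <- config$spec
    spec$seed <- stage_seeds$simulate
    cohort <- generate_cohort(spec)
    table <- cohort$abundance
    clinical <- cohort$clinical
    tree <- cohort$tree
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
  }

  # --- QC + stratification ------------------------------------------------
  table <- filter_low_depth(table, config$min_depth)
  clinical <- clinical[match(rownames(table$values), clinical$sample_id), ]
  clinical <- drop_incomplete(clinical)
  table <- abundance_table(
    table$values[rownames(table$values) %in% clinical$sample_id, ,
                 drop = FALSE], mode = "counts")
  groups <- assign_groups(clinical, cutoffs = config$cutoffs)
  clinical <- clinical[, setdiff(names(clinical),
                                 c("homa_ir", "ir_status", "subgroup"))]
  clinical <- cbind(clinical, groups[, c("homa_ir", "ir_status", "subgroup")])

  # --- diversity ----------------------------------------------------------
  div <- alpha_diversity_report(table, clinical$fl_label, tree = tree)
  utils::write.csv(div$per_sample,
                   file.path(config$out_dir, "diversity_per_sample.csv"),
                   row.names = FALSE)
  utils::write.csv(div$tests,
                   file.path(config$out_dir, "diversity_tests.csv"),
                   row.names = FALSE)

  # --- stratum selection + split -----------------------------------------
  keep <- if (config$group == "ALL") rep(TRUE, nrow(clinical))
          else clinical$ir_status == config$group
  if (sum(keep) < 10) stop("stage stratify: too few samples in stratum ",
                           config$group)
  rel <- relative_abundance(table)
  X <- rel$values[keep, , drop = FALSE]
  yl <- factor(clinical$fl_label[keep], levels = c("NF", "FL"))
  cl_sub <- clinical[keep, ]
  if (min(table(yl)) < 4) stop("stage split: a class is too small")
  sp <- stratified_split(yl, config$train_fraction, seed = stage_seeds$split)
  X_tr <- X[sp$train, , drop = FALSE]; y_tr <- yl[sp$train]
  X_te <- X[sp$test, , drop = FALSE]; y_te <- yl[sp$test]

  # --- sequential feature curve ------------------------------------------
  curve <- sequential_feature_curve(
    X_tr, y_tr, ks = config$feature_ks[config$feature_ks <= ncol(X_tr)],
    folds = min(config$cv_folds, min(table(y_tr))),
    repeats = config$cv_repeats,
    params = config$rf_params, seed = seed, X_test = X_te, y_test = y_te)
  utils::write.csv(curve, file.path(config$out_dir, "feature_curve.csv"),
                   row.names = FALSE)

  # --- GA selection + final refit ----------------------------------------
  ga_cfg <- config$ga; ga_cfg$seed <- stage_seeds$ga
  fit_sp <- config$fit; fit_sp$seed <- stage_seeds$ga
  ga_res <- run_ga(X_tr, y_tr, ga = ga_cfg, fit = fit_sp)
  utils::write.csv(
    data.frame(generation = seq_along(ga_res$trajectory),
               best_fitness = ga_res$trajectory),
    file.path(config$out_dir, "ga_trajectory.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(selected_genera = colnames(X_tr)[ga_res$best_mask != 0],
         best_score = ga_res$best_score,
         popcount = sum(ga_res$best_mask)),
    file.path(config$out_dir, "ga_winner.json"), auto_unbox = TRUE,
    digits = NA)

  refit_X <- X_tr; refit_y <- y_tr
  if (config$use_smote) {
    sb <- smote_balance(X_tr, y_tr, seed = stage_seeds$smote)
    refit_X <- sb$X; refit_y <- sb$y
  }
  eval_rep <- refit_and_evaluate(ga_res$best_mask, refit_X, refit_y,
                                 X_te, y_te, params = config$rf_params)
  jsonlite::write_json(
    eval_rep[c("auroc", "auroc_ci", "accuracy", "kappa", "f1",
               "threshold", "n", "features")],
    file.path(config$out_dir, "model_evaluation.json"), auto_unbox = TRUE,
    digits = NA)

  # --- clinical-index comparison -----------------------------------------
  idx <- steatosis_indices(cl_sub[sp$test, ], thresholds = config$thresholds)
  preds <- list(garf = eval_rep$model$predict_prob(
                  X_te[, eval_rep$features, drop = FALSE]),
                fli = idx$fli, nafld_lfs = idx$nafld_lfs,
                hsi = idx$hsi, fsi = idx$fsi)
  thr <- c(garf = 0.5, config$thresholds)
  comparison <- compare_predictors(preds, y_te, thresholds = as.list(thr))
  utils::write.csv(comparison,
                   file.path(config$out_dir, "predictor_comparison.csv"),
                   row.names = FALSE)

  # --- manifest -----------------------------------------------------------
  arts <- c("diversity_per_sample.csv", "diversity_tests.csv",
            "feature_curve.csv", "ga_trajectory.csv", "ga_winner.json",
            "model_evaluation.json", "predictor_comparison.csv")
  paths <- file.path(config$out_dir, arts)
  manifest <- list(
    seed = seed, stage_seeds = stage_seeds, group = config$group,
    n_samples = nrow(X), n_train = length(sp$train), n_test = length(sp$test),
    artifacts = as.list(stats::setNames(unname(tools::md5sum(paths)), arts)),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(diversity = div, feature_curve = curve, ga = ga_res,
                 evaluation = eval_rep, comparison = comparison,
                 manifest = manifest))
}
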