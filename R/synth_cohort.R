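# Defaults for the ten biomarker genera the classifier targets: baseline
# NF-arm mean relative abundances (fractions, not percent) and the planted
# signed log2 fold changes toward the fatty-liver arm.
planted_genus_defaults <- function() {
  data.frame(
    genus = c("Christensenellaceae_R7", "Weissella", "UBA1819", "Collinsella",
              "Erysipelatoclostridium", "Lachnospiraceae_UCG004",
              "Fusicatenibacter", "Butyricimonas", "Allisonella",
              "Ruminococcaceae_UCG004"),
    baseline_rel = c(0.00736, 0.00089, 0.00104, 0.00052, 0.00153,
                     0.00219, 0.00216, 0.00111, 0.00008, 0.00020),
    log2fc = c(-1.006, -0.168, -1.967, -0.185, -0.032,
               0.536, 0.823, 0.070, 0.408, 1.229),
    stringsAsFactors = FALSE
  )
}

# Group-level clinical covariate targets (mean, sd) for the insulin-sensitive
# and insulin-resistant arms of the cohort; male_frac is the male proportion.
clinical_param_defaults <- function() {
  cov <- c("age", "BMI", "waist", "heart_rate", "homa_ir", "glucose",
           "HbA1c", "albumin", "AST", "ALT", "TG", "total_chol",
           "HDL_C", "LDL_C", "SBP", "DBP")
  IS <- matrix(c(44.86, 8.783, 22.87, 2.688, 80.27, 8.219, 61.43, 7.909,
                 1.016, 0.421, 93.04, 12.98, 5.524, 0.441, 4.475, 0.229,
                 20.40, 7.972, 18.83, 12.62, 104.5, 58.55, 193.1, 33.50,
                 58.96, 14.78, 115.7, 30.10, 107.5, 12.55, 69.75, 9.636),
               ncol = 2, byrow = TRUE, dimnames = list(cov, c("mean", "sd")))
  IR <- matrix(c(46.94, 8.526, 26.25, 3.062, 89.98, 7.709, 64.90, 8.608,
                 2.901, 1.521, 107.7, 21.79, 5.814, 0.578, 4.517, 0.241,
                 26.20, 11.02, 34.73, 24.79, 170.3, 103.3, 197.7, 37.83,
                 48.16, 12.96, 121.0, 33.19, 116.0, 13.09, 75.75, 9.717),
               ncol = 2, byrow = TRUE, dimnames = list(cov, c("mean", "sd")))
  # GGT is needed by the fatty liver index but has no cohort-table target;
  # log-normal with a group shift is an extrapolation (see vignette).
  list(IS = IS, IR = IR,
       male_frac = c(IS = 0.5597, IR = 0.8494),
       ggt_meanlog = c(IS = log(22), IR = log(40)),
       ggt_sdlog = c(IS = 0.55, IR = 0.55))
}

#' Specification for a synthetic microbiome + clinical cohort
#'
#' Defines the statistical conditions the generator emulates: the four
#' subgroup sizes of the study cohort, an 87-genus compositional count
#' table with ten planted differentially abundant genera at the published
#' abundance scales, and clinical covariates matching the published
#' group means and SDs, with HOMA-IR coupled to insulin-resistance status.
#'
#' @param n_per_group Named integer vector of subgroup sizes; names from
#'   \{ISNF, ISFL, IRNF, IRFL\}. Defaults to the study's 449/162/38/128.
#' @param n_genera Number of genera (default 87).
#' @param planted_genera Integer indices of the genera carrying the group
#'   effect (default 1:10, named after the ten biomarker genera).
#' @param effect_log2fc Signed log2 shift of each planted genus in the
#'   fatty-liver arm (length = number of planted genera).
#' @param planted_baseline_rel Baseline (NF-arm) mean relative abundance of
#'   each planted genus.
#' @param baseline_sd SD of the latent per-sample log-abundance noise
#'   (natural-log scale, default 1).
#' @param sequencing_depth_range Integer range of per-sample library sizes.
#' @param effect_subgroups Subgroups receiving the planted shift (default
#'   "IRFL": the signal lives in the insulin-resistant arm only, mirroring
#'   the study's finding that the insulin-sensitive classifier fails).
#' @param clinical_params Group-level covariate targets; see
#'   `clinical_param_defaults()`.
#' @param cutoffs Sex-specific HOMA-IR cutoffs used for the IR coupling.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_group = c(ISNF = 449, ISFL = 162,
                                           IRNF = 38, IRFL = 128),
                           n_genera = 87,
                           planted_genera = 1:10,
                           effect_log2fc = NULL,
                           planted_baseline_rel = NULL,
                           baseline_sd = 1,
                           sequencing_depth_range = c(10000, 30000),
                           effect_subgroups = "IRFL",
                           clinical_params = clinical_param_defaults(),
                           cutoffs = c(M = 1.8, F = 2.2),
                           seed = 1) {
  defs <- planted_genus_defaults()
  np <- length(planted_genera)
  if (is.null(effect_log2fc))
    effect_log2fc <- rep_len(defs$log2fc, np)
  if (is.null(planted_baseline_rel))
    planted_baseline_rel <- rep_len(defs$baseline_rel, np)
  if (any(n_per_group <= 0) || !all(names(n_per_group) %in%
                                    c("ISNF", "ISFL", "IRNF", "IRFL")))
    stop("n_per_group must be positive counts named from ISNF/ISFL/IRNF/IRFL")
  if (anyDuplicated(planted_genera) || any(planted_genera > n_genera) ||
      any(planted_genera < 1))
    stop("planted_genera must be unique indices in 1..n_genera")
  if (length(effect_log2fc) != np)
    stop("effect_log2fc must have one entry per planted genus")
  if (length(planted_baseline_rel) != np || any(planted_baseline_rel <= 0) ||
      sum(planted_baseline_rel) >= 1)
    stop("planted_baseline_rel must be positive fractions summing below 1")
  if (baseline_sd < 0) stop("baseline_sd must be >= 0")
  genus_ids <- sprintf("genus_%03d", seq_len(n_genera))
  genus_ids[planted_genera] <- rep_len(defs$genus, np)
  structure(list(
    n_per_group = n_per_group, n_genera = n_genera,
    genus_ids = genus_ids,
    planted_genera = planted_genera, effect_log2fc = effect_log2fc,
    planted_baseline_rel = planted_baseline_rel,
    baseline_sd = baseline_sd,
    sequencing_depth_range = sequencing_depth_range,
    effect_subgroups = effect_subgroups,
    clinical_params = clinical_params, cutoffs = cutoffs,
    seed = seed
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>",
      sum(x$n_per_group), "samples (",
      paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group), collapse = ", "),
      "),", x$n_genera, "genera,", length(x$planted_genera),
      "planted, seed", x$seed, "\n")
  invisible(x)
}

generate_labels <- function(spec) {
  rep(names(spec$n_per_group), spec$n_per_group)
}

#' Generate a compositional genus count table with planted group effects
#'
#' Latent per-genus log-abundances are normal around genus-specific
#' baselines; planted genera are shifted by `log(2) * effect_log2fc` in the
#' affected subgroups; latents are exponentiated, closed to a composition,
#' and sampled multinomially to an integer library size.
#'
#' @param spec A `synthetic_spec`.
#' @param labels Optional subgroup labels (default: generated from the spec).
#' @return List with `table` (counts-mode `abundance_table`), `labels`, and
#'   `truth` (planted genus ids and effects).
#' @export
generate_abundance <- function(spec, labels = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(labels)) labels <- generate_labels(spec)
  n <- length(labels)
  G <- spec$n_genera
  if (spec$sequencing_depth_range[1] < G)
    stop("sequencing depth below the number of genera: multinomial degenerate")
  set.seed(derive_seed(spec$seed, "abundance"))
  # Baseline composition: planted genera pinned at their published NF-arm
  # means; the remainder drawn once from a heavy-tailed log-normal and
  # rescaled to fill the residual mass.
  base_rel <- numeric(G)
  base_rel[spec$planted_genera] <- spec$planted_baseline_rel
  others <- setdiff(seq_len(G), spec$planted_genera)
  raw <- exp(rnorm(length(others), 0, 1.0))
  base_rel[others] <- raw / sum(raw) * (1 - sum(spec$planted_baseline_rel))
  mu <- log(base_rel)
  shift <- numeric(G)
  shift[spec$planted_genera] <- spec$effect_log2fc * log(2)
  affected <- labels %in% spec$effect_subgroups
  depths <- sample(seq(spec$sequencing_depth_range[1],
                       spec$sequencing_depth_range[2]), n, replace = TRUE)
  counts <- matrix(0L, n, G,
                   dimnames = list(sprintf("S%04d", seq_len(n)), spec$genus_ids))
  for (i in seq_len(n)) {
    lat <- mu + rnorm(G, 0, spec$baseline_sd)
    if (affected[i]) lat <- lat + shift
    p <- exp(lat - max(lat))
    counts[i, ] <- stats::rmultinom(1, depths[i], p / sum(p))[, 1]
  }
  storage.mode(counts) <- "double"
  list(table = abundance_table(counts, mode = "counts"),
       labels = labels,
       truth = list(planted_genera = spec$genus_ids[spec$planted_genera],
                    effect_log2fc = spec$effect_log2fc))
}

#' Generate clinical covariates matching group-level targets
#'
#' Each covariate is drawn per insulin-resistance arm from a normal
#' truncated at physiologic lower bounds; glucose and insulin are coupled
#' through HOMA-IR so that the recomputed index falls on the correct side
#' of the sex-specific cutoff, with the truncated-normal location
#' calibrated so the realized group mean matches the target mean.
#'
#' @param spec A `synthetic_spec`.
#' @param labels Subgroup labels (ISNF/ISFL/IRNF/IRFL), one per sample.
#' @return Data frame of clinical records (one row per sample) with
#'   `sex`, the covariates, derived flags (`diabetes`, `hypertension`,
#'   `mets`) and the ultrasonography label `fl_label`.
#' @export
generate_clinical <- function(spec, labels = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(labels)) labels <- generate_labels(spec)
  if (!all(labels %in% c("ISNF", "ISFL", "IRNF", "IRFL")))
    stop("labels must be study subgroups")
  cp <- spec$clinical_params
  for (arm in c("IS", "IR")) {
    if (is.null(cp[[arm]])) stop("missing covariate parameters for arm ", arm)
  }
  n <- length(labels)
  arm <- substr(labels, 1, 2)
  set.seed(derive_seed(spec$seed, "clinical"))
  sex <- ifelse(runif(n) < unname(cp$male_frac[arm]), "M", "F")

  draw <- function(cov, lower = 0.01) {
    out <- numeric(n)
    for (a in c("IS", "IR")) {
      idx <- arm == a
      pm <- cp[[a]]
      if (!cov %in% rownames(pm)) stop("missing covariate parameters: ", cov)
      out[idx] <- rtruncnorm(sum(idx), pm[cov, "mean"], pm[cov, "sd"],
                             lower = lower)
    }
    out
  }

  rec <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    subgroup = labels, sex = sex,
    age = draw("age", lower = 18),
    BMI = draw("BMI", lower = 12),
    waist = draw("waist", lower = 40),
    heart_rate = draw("heart_rate", lower = 30),
    glucose = draw("glucose", lower = 40),
    HbA1c = draw("HbA1c", lower = 3),
    albumin = draw("albumin", lower = 1),
    AST = draw("AST", lower = 5),
    ALT = draw("ALT", lower = 3),
    TG = draw("TG", lower = 20),
    total_chol = draw("total_chol", lower = 80),
    HDL_C = draw("HDL_C", lower = 15),
    LDL_C = draw("LDL_C", lower = 30),
    SBP = draw("SBP", lower = 70),
    DBP = draw("DBP", lower = 40),
    stringsAsFactors = FALSE
  )
  # HOMA-IR: truncated to the correct side of the sex cutoff, location
  # calibrated so the truncated mean hits the group target; insulin is
  # back-computed so compute_homa_ir() reproduces the draw exactly.
  homa <- numeric(n)
  for (a in c("IS", "IR")) {
    pm <- cp[[a]]
    if (!"homa_ir" %in% rownames(pm)) stop("missing covariate parameters: homa_ir")
    for (s in c("M", "F")) {
      idx <- arm == a & sex == s
      if (!any(idx)) next
      cut <- unname(spec$cutoffs[s])
      lo <- if (a == "IR") cut else 0.05
      hi <- if (a == "IR") Inf else cut
      mu <- calibrate_truncnorm_location(pm["homa_ir", "mean"],
                                         pm["homa_ir", "sd"], lo, hi)
      homa[idx] <- rtruncnorm(sum(idx), mu, pm["homa_ir", "sd"], lo, hi)
    }
  }
  rec$insulin <- homa * 405 / rec$glucose
  rec$GGT <- exp(rnorm(n, unname(cp$ggt_meanlog[arm]),
                       unname(cp$ggt_sdlog[arm])))
  rec$fl_label <- ifelse(grepl("FL$", labels), "FL", "NF")
  # Flags coded by standard clinical thresholds on the synthesized labs.
  rec$diabetes <- rec$glucose >= 126
  rec$hypertension <- rec$SBP >= 140 | rec$DBP >= 90
  rec$mets <- with(rec,
    (ifelse(sex == "M", waist > 90, waist > 80)) +
    (TG >= 150) +
    (ifelse(sex == "M", HDL_C < 40, HDL_C < 50)) +
    (SBP >= 130 | DBP >= 85) +
    (glucose >= 100)) >= 3
  rec
}

#' Generate a random rooted genus phylogeny
#'
#' A rooted binary tree over the genus ids with positive branch lengths,
#' used by Faith's phylogenetic diversity; serializable to Newick.
#'
#' @param n_genera Number of leaves (>= 2).
#' @param seed Integer seed.
#' @param genus_ids Optional leaf labels (default `genus_001`...).
#' @return An `ape::phylo` tree.
#' @export
generate_tree <- function(n_genera, seed = 1, genus_ids = NULL) {
  if (n_genera < 2) stop("need at least 2 genera for a tree")
  if (is.null(genus_ids)) genus_ids <- sprintf("genus_%03d", seq_len(n_genera))
  stopifnot(length(genus_ids) == n_genera)
  set.seed(derive_seed(seed, "tree"))
  tr <- ape::rtree(n_genera, rooted = TRUE, tip.label = genus_ids,
                   br = function(k) runif(k, 0.05, 1))
  tr
}

#' Generate a complete synthetic cohort
#'
#' Abundance table, clinical records, subgroup labels, phylogeny, and the
#' ground-truth planted signal, all driven by the spec's seed.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `abundance`, `clinical`, `labels`, `tree`, `truth`.
#' @export
generate_cohort <- function(spec) {
  ab <- generate_abundance(spec)
  cl <- generate_clinical(spec, ab$labels)
  tr <- generate_tree(spec$n_genera, seed = spec$seed,
                      genus_ids = spec$genus_ids)
  list(abundance = ab$table, clinical = cl, labels = ab$labels,
       tree = tr, truth = ab$truth)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits the abundance TSV, metadata CSV, Newick tree, and a truth JSON
#' (planted genera and effects) into `dir`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             metadata = file.path(dir, "metadata.csv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  write_abundance(cohort$abundance, paths["abundance"])
  utils::write.csv(cohort$clinical, paths["metadata"], row.names = FALSE)
  ape::write.tree(cohort$tree, paths["tree"])
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
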