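# flgarf

Genetic-algorithm-optimized random-forest classification of fatty liver
disease from genus-level gut-microbiome abundances, for cohorts stratified
by insulin resistance.

## What problem this solves

Fatty liver disease in insulin-resistant individuals is where a cheap,
non-invasive biomarker matters most, and stool 16S profiles are an
attractive substrate. The hard part is feature selection: with ~87 genera
and a small insulin-resistant stratum, exhaustive subset search is
impossible and greedy importance ranking plateaus. `flgarf` implements a
genetic-algorithm wrapper around a random-forest classifier that searches
binary genus masks directly, scoring each candidate subset with a
penalized cross-validated AUROC:

    fitness = 100 * mean(S_1..S_M) - W * |x - b|

where `S_k` is the AUROC of the forest on fold `k` of an M-fold stratified
cross-validation restricted to the masked genera, `x` is the subset size,
`b` the target biomarker count (6–10), and `W` the penalty weight
(defaults M = 3, W = 10, b = 10). The maximum, 100, requires perfect fold
AUROCs at exactly the target subset size.

Around that core the package provides the full study-style workflow:
depth QC and HOMA-IR stratification (sex-specific cutoffs 1.8/2.2,
strictly greater), alpha/beta diversity (Shannon, Pielou, Faith's PD,
Bray–Curtis + PCoA) with rank-based group tests, stratified split /
zero-variance + z-score preprocessing / SMOTE / repeated-CV machinery, a
Gini-importance sequential feature curve, four clinical steatosis indices
(FLI, NAFLD-LFS, HSI, FSI) as comparators, and a synthetic cohort
generator (compositional counts with planted log2 fold changes, clinical
covariates with HOMA-IR coupled to group membership) so the entire
pipeline is testable without restricted data.

## Worked example

Simulate an insulin-resistant two-arm cohort at the study geometry
(38 IRNF / 128 IRFL, 87 genera, ten planted genera), then search for a
10-genus biomarker panel:

```r
library(flgarf)

spec <- synthetic_spec(n_per_group = c(IRNF = 38, IRFL = 128), seed = 42)
cohort <- generate_cohort(spec)
rel <- relative_abundance(filter_low_depth(cohort$abundance))
y <- factor(cohort$clinical$fl_label, levels = c("NF", "FL"))

sp <- stratified_split(y, 0.8, seed = 42)
ga <- run_ga(rel$values[sp$train, ], y[sp$train],
             ga = ga_config(population_size = 50, generations = 30, seed = 42),
             fit = fitness_spec(M = 3, W = 10, b = 10, num_trees = 100, seed = 42))
ev <- refit_and_evaluate(ga$best_mask,
                         rel$values[sp$train, ], y[sp$train],
                         rel$values[sp$test, ], y[sp$test],
                         params = list(seed = 42))
```

Output from this exact script:

```
best fitness: 93.1 | genera selected: 10
 [1] "Christensenellaceae_R7" "UBA1819"                "Collinsella"
 [4] "Ruminococcaceae_UCG004" "genus_038"              "genus_041"
 [7] "genus_042"              "genus_064"              "genus_072"
[10] "genus_074"
test AUROC 0.86 (95% CI 0.70-0.98), accuracy 0.88, kappa 0.60, F1 0.93
```

Reading it: the GA converged to a mask of exactly `b = 10` genera (the
size penalty held), its best training fitness of 93.1 corresponds to a
mean fitness-CV AUROC of ~0.93, and the refit forest reached 0.86 AUROC
on the 20% held-out samples. Four of the ten selected genera are planted
signal carriers; the strongest planted effects (|log2FC| ≈ 1–2) are
reliably recovered while the weakest (|log2FC| < 0.2) are not
distinguishable from noise at n = 133 training samples — which is the
expected behaviour, not a defect.

The one-call version of the whole workflow (simulate → QC → stratify →
diversity → feature curve → GA → refit → index comparison, with a
manifest of seeds and artifact hashes):

```r
res <- run_pipeline(run_config(out_dir = "runs/demo", group = "IR", seed = 1))
res$comparison   # AUROC/accuracy/kappa/F1 for the classifier + FLI/NAFLD-LFS/HSI/FSI
```

## Package layout

- `R/synth_cohort.R` — synthetic cohort generator (spec, abundances,
  clinical covariates, phylogeny, writers)
- `R/io_qc.R` — abundance-table container + TSV IO, depth QC, HOMA-IR,
  subgroup assignment
- `R/diversity.R` — Shannon, Pielou, Faith's PD, Bray–Curtis, PCoA,
  rank-based group tests
- `R/ml_core.R`, `R/rf_engine.R` — split/preprocess/SMOTE/metrics and the
  RF engine, repeated CV, feature curve
- `R/ga_select.R` — the penalized-fitness GA (the core method)
- `R/clinical_indices.R` — FLI, NAFLD-LFS, HSI, FSI + comparator table
- `R/pipeline.R` — end-to-end orchestration with manifest
- `vignettes/flgarf-methods.Rmd` — model, assumptions, parameter
  rationale, limitations
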