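---
title: "Methods: GA-optimized random-forest classification of fatty liver from gut microbiome genera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA-optimized random-forest classification of fatty liver from gut microbiome genera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the approach

Fatty liver disease (FL) in insulin-resistant (IR) individuals is the
setting where a non-invasive microbiome biomarker is most valuable:
IR carries the highest risk of progression, while ultrasonography — the
usual screen — is operator-dependent and insensitive to mild steatosis.
`flgarf` implements a classification workflow that asks whether a small
set of gut microbial genera can separate fatty-liver from non-fatty-liver
individuals within the IR stratum of a health-screening cohort.

The workflow is:

1. **QC and stratification.** Samples with a total assigned read count
   below 5000 are dropped. Insulin resistance is assigned by HOMA-IR
   (glucose [mg/dL] x insulin [uIU/mL] / 405) strictly above a
   sex-specific cutoff (1.8 for men, 2.2 for women); crossing IR/IS with
   the fatty-liver label yields four subgroups (ISNF, ISFL, IRNF, IRFL).
2. **Diversity description.** Shannon entropy (base 2), Pielou's
   evenness, Faith's phylogenetic diversity, and Bray–Curtis
   dissimilarity with classical PCoA, compared across groups with
   two-sided Wilcoxon rank-sum (two groups) or Kruskal–Wallis (more).
3. **Baseline classifier.** An 80/20 stratified split; zero-variance
   removal plus z-scoring fit on training data only; SMOTE rebalancing of
   the training partition; a random forest under 10-fold, 3-repeat
   stratified cross-validation; a sequential feature curve over the
   top-k genera ranked once by Gini importance (k = 2, 4, 8, 12, 16, 24,
   32).
4. **GA feature selection.** A genetic algorithm over binary genus masks
   maximizing the penalized cross-validated-AUROC fitness

   $$\mathrm{fitness} = 100 \times \frac{\sum_{k=1}^{M} S_k}{M}
     - W \, |x - b|$$

   where $S_k$ is the AUROC of the random forest on fold $k$ of an
   $M$-fold stratified CV restricted to the selected genera, $x$ is the
   number of selected genera, $b$ the target subset size, and $W$ the
   penalty weight. Defaults: $M = 3$, $W = 10$, $b = 10$ (with
   $b \in \{6,\dots,10\}$ swept by `select_b()`). The analytic maximum is
   100, attained only when every fold AUROC is 1 and $x = b$.
5. **Final evaluation.** The winning mask is refit on the full training
   partition (optionally SMOTE-rebalanced) and evaluated once on the
   held-out test partition by AUROC (with a stratified-bootstrap CI),
   accuracy, Cohen's kappa, and F1, alongside four clinical steatosis
   indices (FLI, NAFLD-LFS, HSI, FSI) computed from the same test
   samples.

## The genetic algorithm

Individuals are binary masks over the $G = 87$ genera. The schedule
defaults mirror the study design: population 300, crossover rate 0.8,
per-bit mutation rate 0.003, 100 generations, single-individual elitism.
Several operator choices were genuinely open and are resolved as follows:

* **Selection**: tournament of size 3 (scale-free and robust to the
  negative scores the penalty can produce); roulette-wheel selection is
  available as an option.
* **Crossover**: uniform by default; one-point available. The crossover
  rate is the probability that a selected pair is recombined at all.
* **Mutation**: interpreted per bit (0.003 x 87 ≈ 0.26 flips per
  individual), the common GA convention.
* **Initialization**: bits i.i.d. Bernoulli($b/G$), so the expected
  popcount starts at the target subset size and the penalty term starts
  near zero. A 0.5 inclusion probability is available via `init_p`.
* **Elitism ties** are broken by lowest population index, and Gini-ranking
  ties in the feature curve by feature id order, for determinism.
* **Empty masks** score $-\infty$ so they can never be selected.
* **Fitness CV folds** are re-drawn each generation but shared by every
  individual within a generation: within a generation, fitness
  differences reflect the masks rather than fold noise, while across
  generations no single fold split can be adaptively overfit (with one
  fixed split for a whole run, a GA on pure noise can climb to fitness
  values well above the chance level of 50 by exploiting that split).
  Distinct masks are memoized within each generation.
* **Generation count**: the study description is ambiguous between 100
  and 300 generations; the default is 100 and the value is configurable.
* **SMOTE inside the fitness CV**: not applied by default. Rebalancing is
  applied (when enabled) to the final refit's training data only; the
  held-out test partition never receives synthetic samples.

## The synthetic cohort generator

The study's sequencing data sit in a restricted national archive, so the
package ships a generator that reproduces the *statistical structure* the
analysis assumes and makes every downstream stage testable.

**Abundances.** Each genus has a latent baseline log-abundance; per-sample
latents add N(0, `baseline_sd`) noise, are exponentiated, closed to a
composition, and sampled multinomially at a library size drawn uniformly
from `sequencing_depth_range` (default 10,000–30,000 reads, comfortably
above the 5000-read QC cutoff). Ten planted genera carry the published
group effects: their baselines are pinned at the published IRNF mean
relative abundances (0.008%–0.736%) and their latents are shifted by
log2-fold-changes of −1.967 to +1.229 in the affected arm. The remaining
77 baselines are drawn once from a heavy-tailed log-normal and rescaled to
fill the residual mass. Two generator choices are the package's own:
`baseline_sd = 1` and a log-normal spread of 1.0 for the non-planted
baselines, which give genus-level evenness around 0.75–0.8 — realistic for
genus-aggregated gut tables, where a few dominant genera always depress
evenness below ASV-level values.

The planted shift is applied to the IRFL subgroup only (configurable via
`effect_subgroups`): the signal lives in the insulin-resistant arm,
mirroring the study's observation that the insulin-sensitive classifier
fails. A consequence used by the tests: a pipeline run on the IS stratum
of a default cohort should sit at chance.

**Published fold changes vs published means.** The published per-genus
log2 fold changes are not fully consistent with the published group means
(e.g. log2(0.202/0.736) = −1.87, printed −1.006). The generator plants
the printed log2FC values and keeps the printed NF-arm means as baselines;
the discrepancy is inherited from the source tables, not resolved here.

**Clinical covariates.** Covariates are drawn per IR/IS arm from normals
truncated at physiologic lower bounds, with the published group means and
SDs as targets. Glucose and insulin are *coupled*: HOMA-IR is drawn from
a normal truncated to the correct side of the sample's sex-specific
cutoff, and insulin is back-computed as HOMA-IR x 405 / glucose, so
recomputing HOMA-IR from the emitted table reproduces the draw exactly
and group membership is internally consistent. A plain normal with the
published (mean, SD) would put ~32% of IR women below their cutoff, so
consistency and the published moments cannot both hold exactly; the
resolution here calibrates the truncated-normal *location* (by
root-finding on the truncated mean) so the realized group mean matches
the published mean, at the cost of a somewhat smaller realized SD.
Covariates other than (glucose, insulin) are sampled independently — the
generator reproduces group-level contrasts, not the within-group
correlation structure of real labs.

Two fields the indices need are not in the published group table and are
synthesized explicitly as extrapolations: GGT (log-normal, group-shifted,
medians ≈ 22 IU/L IS / 40 IU/L IR) and the diabetes / hypertension /
metabolic-syndrome flags (standard thresholds on the synthesized labs:
glucose ≥ 126 mg/dL; BP ≥ 140/90; ≥ 3 of the five usual MetS components
with Asian waist cutoffs).

**What passing tests do and do not show.** The generator produces
compositional counts with planted mean shifts and group-consistent
covariates; it does not emulate genus–genus correlation, zero inflation
beyond the multinomial, batch effects, or covariate–microbiome coupling.
Recovery results on synthetic cohorts demonstrate that the machinery
finds the kind of signal the study reports at the published effect sizes
and group sizes — not that the published biomarker set is correct.

## Clinical comparator indices

The four indices are computed from their original publications'
coefficient sets (kept in one auditable place, `index_coefficients()`):

* **FLI** = logistic(0.953 ln TG + 0.139 BMI + 0.718 ln GGT +
  0.053 waist − 15.745) x 100, range 0–100.
* **NAFLD-LFS** = −2.89 + 1.18 MetS + 0.45 T2DM + 0.15 insulin +
  0.04 AST − 0.94 AST/ALT.
* **HSI** = 8 ALT/AST + BMI + 2 DM + 2 female.
* **FSI** = logistic(−7.981 + 0.011 age − 0.146 female + 0.173 BMI +
  0.007 TG + 0.593 HTN + 0.789 DM + 1.1 I(ALT/AST ≥ 1.33)), a
  probability.

Units are fixed (mg/dL, IU/L, cm, kg/m²); no automatic conversion is
attempted. Binarization cutoffs for the accuracy/kappa/F1 comparison are
not part of the indices themselves and are reported as an explicit column:
defaults FLI ≥ 60, HSI ≥ 36, NAFLD-LFS ≥ −0.640, FSI ≥ 0.5 (each index's
published rule-in cutoff where one exists), all configurable.

## Numerical and statistical choices

* **AUROC** is computed by mid-ranks (Mann–Whitney concordance), so ties
  contribute 1/2; it is invariant under strictly monotone transforms of
  the scores.
* **Kappa** uses chance agreement from the confusion-matrix marginals and
  is flagged `NA` when chance agreement is exactly 1; F1 is flagged `NA`
  when no positives are predicted or present.
* **Rank tests** delegate to `stats::wilcox.test` / `stats::kruskal.test`
  (mid-ranks, exact enumeration at small n without ties, tie-corrected
  normal approximation otherwise). Constant inputs return p = 1 with a
  warning rather than erroring inside a pipeline.
* **PCoA** eigendecomposes the double-centered matrix symmetrized to
  guard against floating-point asymmetry; negative eigenvalues are
  reported but excluded from the proportion explained; axis signs are
  fixed by making the largest-magnitude loading positive.
* **Random forests** delegate to `ranger` (500 trees,
  `mtry = floor(sqrt(p))`, impurity importance, single-threaded, seeded)
  — the study used default RF settings, and the contract here is
  probability outputs + Gini importances + seeded determinism.
  Gradient-boosted trees (`xgboost`) are available behind the same
  contract as a comparator engine.
* **Truncated normals** are sampled by inverse-CDF, with a far-tail guard
  that returns the nearer bound when the truncation window's mass
  underflows.
* **Seeding**: one user-facing seed fans out to per-stage streams via a
  fixed integer derivation (`derive_seed`), so stages are independently
  reproducible and all derived seeds stay below 2^31.

## Problem sizes used by the test suite

The recovery experiments run on the study's IR-arm geometry (38 IRNF /
128 IRFL, 87 genera) under a reduced GA schedule chosen for desk-scale
runtimes: population 50, 30 generations, M = 3, with 50-tree forests
inside the fitness CV (the 500-tree default is kept for final refits).
Effect-size recovery is checked at 1000 samples per arm with
`baseline_sd = 0.5` and 40–60k read depths, where the Monte-Carlo error
of a realized log2FC is ≈ 0.03, well inside the 0.1 tolerance asserted.
The GA-vs-exhaustive oracle uses 12-genus masks (4096 exhaustive
evaluations) under a deterministic surrogate fitness. The chance-level
band asserted for GA runs on permuted labels ([40, 70] fitness points)
is the winner's-curse bound for the maximum of roughly a thousand
correlated null CV-AUROC means, fixed before the experiments were run.

An important empirical caveat the suite itself surfaces: because the
fitness cross-validation sits *inside* the selection loop, an adaptive
search over 87 genera can assemble masks of chance-correlated genera
whose cross-validated AUROC on a fixed dataset of 166 samples is well
above 0.5 — the classical selection bias of wrapper feature selection.
On label-permuted data the GA's best fitness therefore lands near 75–80
rather than at the naive chance level of 50, and on cohorts with the
published (mostly weak) per-genus effect sizes, noise-augmented masks
can match or beat the true planted subset, limiting how much of the
planted set the winner recovers at this sample size. Only an outer
validation layer (the held-out test partition, which the pipeline keeps
untouched until the final refit) gives an unbiased performance
estimate.

## Known limitations

* The generator's independence assumptions (genus–genus,
  covariate–covariate, covariate–microbiome) are simplifications; see
  above for what recovery results do and do not establish.
* The realized SD of HOMA-IR is below the published SD by construction
  (truncation); the published mean and the cutoff consistency take
  precedence.
* FLI requires GGT, which has no published group parameters in this
  cohort; its synthetic distribution is an explicit extrapolation.
* The comparator engines cover random forests and XGBoost; a
  gradient-boosting-machine (gbm) engine is not provided.
* UMAP ordinations are intentionally out of scope; PCoA covers the
  ordination needs of the workflow.
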