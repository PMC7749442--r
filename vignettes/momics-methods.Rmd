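---
title: "Methods: cohort-adjusted multi-omics modelling of preterm birth"
author: "momics package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-adjusted multi-omics modelling of preterm birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`momics` implements a two-layer ("late integration" / stacked
generalization) analysis of pregnancy multi-omics collected across several
birth cohorts: plasma cell-free RNA transcriptomics, targeted plasma
proteomics and urine metabolomics, measured once per subject early in
pregnancy. Two outcomes are modelled:

* **Chronicity of pregnancy** — gestational age (GA) at the time of
  sampling, in weeks, a continuous target shared across cohorts.
* **Preterm birth (PTB)** — delivery before the completion of 37 weeks of
  gestation (`ga_delivery_weeks < 37`, strictly; 37.0 is term). The flag is
  always derived from the delivery age, never read from a file.

The guiding statistical assumptions, which the synthetic-data generator
makes explicit, are:

1. Each modality is internally correlated (low effective rank), with the
   transcriptome the most redundant despite having the most features.
   Because the modalities differ by orders of magnitude in size, a single
   pooled model would let the largest assay dominate; one model per
   modality plus a second-layer combiner avoids that.
2. Cohorts carry subtle batch signatures — detectable by a supervised
   learner but not dominating the overall variance structure.
3. The chronicity signal is shared across cohorts; the PTB signal is only
   partially shared, with cohort-specific components that make
   cohort-conditioning steps necessary.
4. Urine metabolomics, and only urine metabolomics, is confounded by sample
   storage time.

## The pipelines

### GA estimation (`predictGACV`)

Outer 10-fold cross-validation over subjects. Per outer training set and
modality, an L1-penalized linear model (lasso; `glmnet`) with its penalty
chosen by inner 5-fold cross-validation predicts the held-out fold. The
integration layer is a non-negative least-squares (NNLS) combination of the
per-modality estimates, fit exclusively on out-of-fold estimates generated
*inside* the outer training set — the second layer of the two-layer scheme —
so no subject's GA ever reaches a model that scores that subject.
Non-negativity prevents the combiner from exploiting sign-flipped noise.

Pooled out-of-fold estimates carry fold-specific baselines (each outer
model sees a slightly different training mean). Under a pure null this
induces a systematic *negative* Spearman correlation between estimates and
truth — each fold's constant is anti-correlated with the fold's outcomes —
so all estimates are centred within their outer fold before evaluation and
are reported relative to the cohort mean. With genuine signal the effect of
centring on Spearman performance is negligible, because most GA variance
lies within folds.

Spearman correlations are reported raw and Bonferroni-adjusted with factor
4 (three modalities plus the integrated model). Spearman p-values use the
large-sample t approximation, switching to exact permutation below n = 10.

### PTB classification (`loocvPredict`)

Leave-one-out cross-validation. For each held-out subject and modality:

1. **Per-cohort z-scoring** with training-set statistics (a cohort whose
   training members are all one class still contributes its own location
   and scale).
2. **Cohort-restricted feature selection**: features ranked by a Wilcoxon
   rank-sum test computed only on training subjects from the held-out
   subject's cohort; up to `k_top` (default 50) are kept. Ties are broken
   by absolute rank-biserial effect, then feature id, so selection is
   deterministic. If that cohort lacks two training members in either
   class, selection falls back to the pooled training set (logged and
   counted).
3. **L2-regularized logistic model** (`glmnet`, ridge) on the selected
   features, penalty chosen by stratified inner 5-fold cross-validation
   over a fixed 12-point grid. All classification fits use balanced class
   weights (each class carries half the total weight): without them,
   leave-one-out training sets are tilted against the held-out subject's
   class, which biases the null AUROC below 0.5.

The integration layer is a logistic model of the three per-modality
probabilities with *non-negative* modality weights and one intercept per
cohort, fit by box-constrained quasi-Newton optimisation of the balanced
class-weighted likelihood with a small ridge penalty for stability. As in the GA pipeline it is trained only on
out-of-fold probabilities generated inside the outer training set (inner
5-fold). To keep leave-one-out affordable, the inner first-layer fits reuse
the outer training set's z-scoring statistics, pooled univariate screen and
chosen penalty; these quantities never involve the held-out subject, so the
leak-freedom property (mutating a held-out subject's label cannot change
its own prediction) holds exactly and is verified by a mutation test.

AUROC is computed as the scaled Mann-Whitney statistic (ties count one
half) with a stratified bootstrap percentile 95% CI (default 2000
resamples). The supporting analyses are: a class-size-preserving
random-label control (the whole pipeline repeated on permuted labels,
expected AUROC 0.5); comparator strategies under identical leave-one-out
splits (merged-feature ridge, lasso and random forest, plain stacking
without any cohort conditioning, and the full cohort-adjusted pipeline);
and a covariate confounding screen correlating the integrated probability
with every clinical covariate (Benjamini-Hochberg adjusted; only
delivery age and the delivery-age-derived birthweight should survive).

### Feature statistics and enrichment

Per-feature PTB association uses the linear mixed model
`value ~ ptb + (1 | cohort)` fit by REML (`lme4`), with a Wald normal
p-value for the PTB coefficient; Wald was preferred to a likelihood-ratio
test because the model is refit for every feature. Values are standardized
first so the coefficient reads as a standardized mean difference
(`standardize = FALSE` recovers the raw-scale effect, which is what the
parameter-recovery tests assert). Singular fits (cohort variance collapsing
to zero) fall back to OLS and are flagged. A two-sided Wilcoxon rank-sum
test is reported alongside (exact when the smaller class has at most 8
members and there are no ties). Benjamini-Hochberg adjustment is applied
within modality — feature counts differ by orders of magnitude and pooling
would drown the smallest assay.

Correlated modules among top features are connected components (size >= 3)
of the graph with edges at absolute Spearman correlation >= 0.6. Pathway
over-representation is the one-sided hypergeometric (Fisher) upper tail.

### Structural QC

* `modalityComplexity`: components needed for 90% of the variance of the
  standardized matrix.
* `pcaEmbedding` / `ldaEmbedding`: unsupervised and cohort-supervised 2-D
  views. LDA shrinks the within-class scatter toward a scaled identity
  (`gamma = 0.1`) because features far outnumber subjects.
* `cohortPredictability` / `storageTimePredictability`: 5-fold
  cross-validated random forests (500 trees by default) predicting cohort
  or storage time, with add-one permutation p-values
  `(1 + #{null >= obs}) / (1 + n_perm)` in which every permutation re-runs
  the full cross-validated fit.
* `correlationNetworkEmbedding`: t-SNE on the distance `1 - |rho|` between
  all feature pairs (Spearman). The embedding is computed by an exact
  quadratic-time t-SNE implemented in the package (perplexity calibration
  by bisection, early exaggeration, momentum gradient descent), fully
  deterministic given the seed. Perplexity defaults to 30, capped at
  `(n_features - 1) / 3`.

## The synthetic-data generator

The generator (`generateDataset`) defines the study conditions: 81
subjects in 5 balanced cohorts, exactly 39 preterm (the case count is
enforced by construction, not binomial sampling, so it is a deterministic
property), maternal age 24.8 (5.3) years, sampling centred at 13.6 weeks,
delivery ages from truncated normals on either side of 37 weeks, storage
times uniform on 100-1000 days and drawn independently of delivery age.
Full-preset dimensionalities are 20659 / 1002 / 6630
(transcriptomics / proteomics / metabolomics); the fast preset
(200 / 100 / 150) is statistically identical and is what the tests and the
acceptance analyses use, keeping the whole suite within desk-scale run
times (problem sizes: leave-one-out over 81 subjects, 10 evaluation seeds,
20 label permutations).

Per modality, values are built from:

* a **latent factor backbone** — rank 3 / 8 / 15 with per-feature latent
  sd 2.2 / 1.35 / 1.0 — chosen so that the transcriptome is the most
  internally correlated and its latent block alone crosses the 90%
  variance mark, reproducing the inverse relation between assay size and
  component count;
* **cohort batch shifts**, iid N(0, 0.3) per (cohort, feature): large
  enough for a cross-validated random forest to detect, small enough that
  the cohorts do not separate in the top two principal components
  (silhouette < 0.1);
* a **GA module**: 20 / 10 / 20 features with coefficient ±0.3 per week on
  the centred sampling age, identical in every cohort (the chronicity
  signal is shared). One GA-informative proteomics feature is named `PGF`
  so the urine-surrogate analysis has its target;
* a **PTB module**: 20 / 8 / 15 features forming one correlated block per
  modality, driven by a subject-level activity (sd 1) whose case shift is
  2.5 activity-sds. A fraction `h = 0.5` of the shift is drawn per cohort,
  and cohorts also differ in the module's baseline activity (sd `h`
  times the shift). The module structure keeps univariate case contrasts
  strong while bounding the multivariate information at realistic AUROCs —
  a plain additive design saturates every classifier at AUROC 1 — and
  mirrors the empirical observation that top PTB features form correlated
  modules. Setting `h = 0` removes both cohort-specific components, which
  is what makes cohort adjustment provably vacuous in that condition;
* a **storage confound** on a random 10% of metabolomics features only
  (±0.6 per sd of storage time);
* iid noise, sd 0.6.

Magnitudes were calibrated once, before freezing the test suite, to sit in
the regime the analysis is designed for — detectable but not saturated
signal, batch effects subtle, cohort adjustment beneficial when and only
when the PTB signal is partially cohort-specific — and are deliberately not
derived from any real dataset. What the passing tests show is therefore
that the *pipeline* behaves correctly under these conditions (recovers
planted structure, centres at chance under permuted labels, never leaks
outcomes); they say nothing about real cfRNA count distributions, real
proteomic panels or real metabolite chemistry, none of which the generator
attempts to emulate.

`generatePathways` plants one pathway containing at least 70% of the
preterm-informative metabolite features among uniformly drawn decoys
(sizes 10-50), for end-to-end enrichment recovery tests.

## Numerical and design choices

* All randomness is derived from explicit integer seeds via a deterministic
  child-seed stream; identical configurations give bit-identical results.
* Zero-variance features are dropped (QC, screening) or given unit scale
  (z-scoring) rather than producing NaNs; constant features are skipped and
  logged in the ranking functions.
* Selection ties break by effect size then feature id; module ids are
  numbered by decreasing size; result tables have deterministic orderings.
* The equal-weight fallback of the integration layer fires only when every
  modality's probabilities are constant (degenerate inputs).
* Outer folds reduce with a warning when subjects are too few
  (`n < 2 x folds`); cohort-restricted selection falls back to pooled
  selection when the test cohort lacks both classes among training
  subjects.
* `k_top = 50` per modality: large enough that the planted modules fit with
  room for noise, small relative to the feature space; configurable.
* Wilcoxon screening inside cross-validation uses the continuity-corrected
  normal approximation throughout (only the ordering matters there); the
  user-facing `wilcoxonFeatureTest` switches to exact enumeration for
  small tie-free samples.

## Known limitations

* The generator's Gaussian abundances ignore count over-dispersion,
  missingness patterns and batch-by-storage interactions of real assays.
* With 5 cohorts, the Wald p of the mixed model is slightly liberal in the
  extreme tail; BH-adjusted decisions at q = 0.05 are unaffected in the
  calibration simulations.
* The exact t-SNE is quadratic in feature count; it is meant for the
  reduced feature sets of the fast preset (hundreds of features), not for
  full-preset embedding.
* Cohort-restricted selection needs a handful of both classes per cohort;
  with very small or single-class cohorts the pipeline degrades gracefully
  to pooled behaviour but loses its cohort specificity.
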