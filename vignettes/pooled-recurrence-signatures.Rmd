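---
title: "Building recurrence signatures from pooled microarray cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building recurrence signatures from pooled microarray cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsig)
```

## The problem

Individual breast-cancer microarray studies are usually too small to select
reproducible prognostic genes: two studies of the same question rarely agree
on their gene lists. Pooling several public cohorts profiled on the same
platform raises the sample size, but introduces two obstacles that this
package addresses end to end:

1. **Cohorts are not on a common scale.** Each laboratory's intensities
   differ in location and spread. We map each cohort's linear intensities
   `X` onto a shared log2 scale by an affine-log conversion
   `Y = log2(a*X + b)`, collapse probes to genes by the per-sample median,
   standardize each gene within its cohort (Z-scores), merge, and quantile
   normalize the merged samples.
2. **Five-year recurrence is only determinable for some subjects.** Subjects
   with missing outcome, positive or unknown lymph-node status, or event-free
   follow-up shorter than five years are removed by an explicit cascade whose
   stage-by-stage counts are reported.

On the harmonized pool the package selects candidate genes by a bootstrap
trimmed-mean Mann-Whitney ranking, compares classifier families
(decision tree, ridge logistic regression, neural networks with and without
over-training prevention, and tree-selected composites) on balanced
train/test splits, and finally assembles an incremental Cox risk signature
whose size is chosen by test-set AUC.

## Synthetic cohorts: what they emulate and what they do not

No public data ships with the package; a generator ([`simulate_cohorts()`])
produces pooled cohorts with a known ground truth so every stage is testable
offline. Its defaults are fixed once and define the package's reference
study conditions:

* **4 cohorts of 198/189/249/286 subjects** (the sizes of the pooled design
  the package emulates), stored on distorted linear scales with affine
  parameters `(1, 0)`, `(2.2, -8)`, `(2.65, -0.1)`, `(1, 0)` — the first
  cohort acts as the log2 reference.
* **2,000 genes covered by 1–14 probes each** (a desk-scale stand-in for a
  22,283-probe/13,452-gene chip). Probe values are the gene's log2 value
  plus a *fixed* per-probe offset (SD 0.3 log2) plus measurement noise
  (SD 0.3 log2). Fixed offsets make the median-collapse rule meaningful: a
  per-sample median over probes that disagree systematically.
* **20 signal genes** forming a co-expressed module: each loads 0.8 on a
  shared latent factor. Co-expression is deliberate, for two reasons. It is
  what real prognostic modules (e.g. proliferation clusters) look like, and
  it is a mathematical necessity: with independent signal genes the mean
  separation per gene between outcome classes is bounded near 0.36 SD no
  matter how strong the hazard, so the 1-SD separation the generator targets
  would be unattainable.
* **Survival** follows an exponential model with hazard
  `h0 * exp(sum(w_g z_g))` over the standardized signal genes
  (`h0 = 0.06`/year). The common weight `w` is *calibrated by quadrature* so
  that the induced mean difference of each signal gene between subjects who
  do and do not relapse within five years equals `effect_size` (default 1.0
  log2 units). Censoring is uniform on (0, 20) years. The implied five-year
  relapse prevalence (about one third) is returned by
  `expected_relapse_prevalence()`.
* **Clinical covariates** (age, tumor size, grade, ER status, node status)
  are independent of expression by default; a `grade_hazard` link is
  available but off. Missing values are injected only into node status and
  relapse status, the two fields the exclusion cascade filters on.

What the generator does **not** emulate: probe-sequence effects and
background chemistry (inputs are assumed background-corrected), platform
annotation errors, treatment effects on outcome, cohort-specific
case mix, and non-proportional hazards. Passing tests therefore demonstrate
that the pipeline's logic is correct under its stated model, not that the
published effect sizes transfer to real arrays.

## Harmonization choices

Several points of the preprocessing recipe are under-determined and were
fixed as follows:

* The affine-log formula is read as `Y = log2(a*X + b)` — the reading where
  `(a, b)` can match both the location *and* the spread of the reference;
  `log2(aX) - c` is a pure shift and cannot adjust dispersion.
* Stage order is affine-log → probe collapse → per-gene Z within cohort →
  merge → quantile normalization. Collapsing after the log keeps the median
  rule on the analysis scale; normalizing after the merge makes the pooled
  samples exchangeable.
* Z-standardization is per gene within cohort; that is the reading under
  which merging gene values across cohorts is meaningful.
* An even probe count collapses to the mean of the two middle values.
* `estimate_affine_params()` recovers `(a, b)` by Nelder-Mead on the squared
  distance between the cohort's post-transform mean/SD and the reference's,
  started at `(1, 0)`; the pipeline uses the known transforms by default and
  estimation is exercised by tests.
* Quantile normalization delegates to `limma::normalizeQuantiles(ties =
  TRUE)`, whose tie convention (tied values share the mean of their ranks'
  reference values) matches the package's contract.

## Gene ranking

`rank_candidate_genes()` draws 200 subjects at random (unstratified; redrawn
if single-class), runs 200 bootstrap rounds (resampling those 200 subjects
with replacement; single-class resamples are redrawn so the round count
stays fixed), computes per-gene two-sided Mann-Whitney p-values per round,
trims the smallest and largest 5% (floor rule: exactly 180 of 200 remain)
and ranks genes by the trimmed mean, breaking ties lexicographically. The
scalar test uses the exact U distribution when both groups have at most 8
observations without ties, otherwise a tie-corrected,
continuity-corrected normal approximation; the bootstrap path is a
vectorized implementation of the same approximation, tested for equality
against the scalar one. No multiple-testing correction is applied — the
ranking is a screening device, not an inference.

## Classifier suite

All classifiers consume the 100 top-ranked genes only; clinical variables
are used for balance checks and Cox adjustment. 400 random 370:387
partitions are drawn, each checked for train-vs-test balance over the 100
genes plus six clinical variables (continuous: Mann-Whitney; categorical:
chi-square), and the 20 best-balanced splits become the cross-validation
sets; reported performance is the mean over those sets.

The model internals of the original tooling are proprietary, so the package
implements the model *roles*: a CART-style tree (Gini, minimum leaf 5,
cost-complexity pruning by internal 10-fold cross-validation with the 1-SE
rule — on pure noise the tree prunes to the root); a ridge logistic
regression (IRLS, penalty 1e-4 on standardized inputs, which keeps
separable fits finite); and a single-hidden-layer perceptron (10 logistic
hidden units, full-batch gradient descent with momentum on cross-entropy,
300-epoch budget, learning rate 0.5). "Over-training prevention" at
fraction `f` holds out `1 - f` of the training rows as an internal
validation set and returns the weights of the epoch with the best
internal-validation accuracy (patience 20); `f = 1` disables it. Composites
(DL, DA80, DA100) fit the tree first and pass its positively important
variables to the head model, falling back to the first 10 ranked genes if
the tree prunes everything away.

Accuracy uses the fixed 0.5 probability threshold; AUC uses the rank
(Mann-Whitney) formulation with midranks, which equals trapezoidal ROC
integration. Importance integration across the four single models is a
Borda mean rank — the published procedure names no integration rule, and
mean rank is the neutral choice — with ties broken by the ranking p-value.

## The incremental Cox signature

Genes enter a standardized Cox model (Efron ties, via the survival package)
one at a time in integrated-importance order, fitted on the training half
of the best-balanced split; train and test subjects are scored with the
training coefficients (test Z-scores reuse training means/SDs — no
re-standardization). The signature size `k*` maximizes the *test* AUC of
the score against the binary five-year relapse label (smallest `k` on
ties); using the binary label rather than a time-dependent ROC matches the
five-year framing of the evaluation criteria. The risk cutoff is the
training-score threshold with the highest specificity among those with
sensitivity at least 0.80; equally specific thresholds are broken toward
the more sensitive one, then the higher value. Threshold candidates are
midpoints of adjacent unique scores plus sentinels beyond both extremes. High/low groups on the test half are compared by
Kaplan-Meier curves, the log-rank test, and univariate plus
clinically-adjusted Cox models (age, tumor size, grade dichotomized at 3,
ER). Reclassification (NRI) compares the high/low assignment of a
clinical-only Cox score with that of a clinical-plus-signature score, both
dichotomized by the same cutoff rule, evaluated on the test half.

```{r, eval = FALSE}
res <- run_recurrence_pipeline(seed = 1)
glance(res)
autoplot(res$signature)   # AUC vs gene count, k* marked
autoplot(res$km)          # Kaplan-Meier curves of the risk groups
```

## Numerical and scale choices

* Problem sizes: the default configuration (4 cohorts, 2,000 genes, 922
  subjects before exclusions) is the package's desk-scale reference design;
  the unit tests use smaller two-cohort designs (60–300 subjects, 150–300
  genes) because every property they check is size-stable.
* Degenerate inputs error loudly rather than silently repair: non-positive
  affine arguments name the offending probe/sample; zero-variance genes
  list their ids; single-class labels, empty trims, and missing covariates
  are all errors.
* The logistic and Cox fits declare convergence at step/score tolerances of
  1e-10 and the survival package's defaults respectively; the ANN is the
  only stochastic fitter, and all of its randomness (init, holdout,
  permutation importance) flows from the function's `seed` argument.
* Every pipeline stage derives its seed from the master seed by fixed
  offsets, so a run is a pure function of `(config, seed)`.

## Known limitations

* The exponential survival model has a constant baseline hazard; the Cox
  stage does not test proportional hazards.
* The generator's log2-normal expression is a stand-in: real array
  distributions are heavier-tailed and probe effects are sequence-driven.
* With 100 candidate genes and ~310 training subjects the unpenalized Cox
  fits at large `k` are noisy; the incremental curve's late section is
  correspondingly unstable, which is precisely the overfitting behaviour
  the `k*` selection exploits.
* NRI is reported for the two-category (high/low) scheme induced by the
  cutoff rule; multi-category or continuous NRI variants are out of scope.
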