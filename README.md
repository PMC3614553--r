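# poolsig

Pooled-cohort gene signatures for five-year breast-cancer recurrence.

Single microarray studies rarely agree on prognostic gene lists; pooling
several cohorts profiled on the same chip raises power, but only after the
cohorts are forced onto a common scale and restricted to subjects whose
five-year outcome is determinable. `poolsig` implements that whole workflow
as composable, pipe-friendly functions plus one end-to-end driver:

1. **Harmonization** — per-cohort affine-log conversion
   `Y = log2(a·X + b)` onto a shared log2 scale, median collapse of probes
   to genes, per-gene Z-standardization within cohort, merge, quantile
   normalization; then an explicit exclusion cascade (missing outcome →
   node-positive/missing → event-free follow-up < 5 years) with
   stage-by-stage counts.
2. **Gene ranking** — 200 random subjects, 200 bootstrap rounds of
   per-gene two-sided Mann–Whitney *U* tests between relapse classes, a 5%
   symmetric trim (exactly 180 of 200 p-values kept), genes ranked by the
   trimmed mean; the top 100 go forward.
3. **Classifier suite** — 400 random 370:387 train/test partitions, the 20
   best-balanced kept as cross-validation sets; decision tree, ridge
   logistic regression, neural networks with (`ANN80`) and without
   (`ANN100`) over-training prevention, and tree-selected composites
   (`DL`, `DA80`, `DA100`), each reported as ACC/AUC (%) on train and test
   with the extrapolation differences ΔACC = ACC_train − ACC_test and
   ΔAUC = AUC_train − AUC_test.
4. **Risk signature** — variable importance integrated across the single
   models by mean rank; genes enter a standardized Cox model one at a time
   in that order; the signature size k\* maximizes test AUC of the risk
   score `Σ βⱼ·zⱼ` against the binary five-year relapse label; a cutoff
   with training sensitivity ≥ 80% and maximal specificity dichotomizes
   subjects into high/low risk, compared by Kaplan–Meier curves, the
   log-rank test, univariate and clinically adjusted hazard ratios
   (HR = exp β) and net reclassification improvement (NRI) over a
   clinical-only risk model.

A synthetic multi-cohort generator (`simulate_cohorts()`) with planted,
co-expressed recurrence genes and exponential survival stands in for the
original public downloads, so everything runs and is tested offline with a
known ground truth.

## Worked example

```r
library(poolsig)

res <- run_recurrence_pipeline(seed = 1)   # default 4-cohort design, ~8 min
res
#> <recurrence_pipeline>
#>   retained subjects: 659
#>   signature size k*:24 (test AUC 0.8683)
#>   high vs low HR: 6.27  log-rank p: 5.39e-40  NRI: 0.633
```

Reading this: of the 922 simulated subjects, 659 survive the exclusion
cascade. The bootstrap ranking recovers all 20 planted recurrence genes in
its top 100. Adding genes to the Cox score in integrated-importance order,
the test-set AUC rises and then falls; it peaks at k\* = 24 genes
(AUC 0.868) — close to the 20 genes actually planted, with the decline
beyond the peak showing the cost of overfitting a longer signature. The
24-gene score dichotomized at the ≥ 80%-sensitivity cutoff splits the test
subjects into risk groups whose relapse-free curves separate decisively
(HR 6.27, log-rank p ≈ 5e-40), and adding the gene score to a
clinical-only Cox model reclassifies a net 63% of subjects in the right
direction (NRI 0.633).

Per-stage results are plain tibbles:

```r
glance(res)                      # one-row run summary
res$suite$summary                # ACC/AUC/Δ per model (Table-style)
tidy(res$signature)              # gene, order, Cox beta, HR
autoplot(res$signature)          # AUC-vs-k curve with k* marked
autoplot(res$km)                 # Kaplan-Meier curves of the risk groups
```

The individual stages are exported (`harmonize_cohorts()`,
`rank_candidate_genes()`, `fit_model_suite()`, `incremental_signature()`,
`hazard_ratios()`, `nri()`, ...) and consume/produce data frames, so custom
cohorts can be run through any sub-sequence; `read_expression()` /
`read_clinical()` load the documented TSV/CSV formats.

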