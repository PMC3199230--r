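# bprsig

Diagnostic gene-expression signatures for whole-lung disease by Bayesian
probit regression (BPR) on SVD metagene factors — with the complete
workflow around the classifier: cohort summaries, unsupervised structure
analysis, empirical-Bayes differential expression, leave-one-out model-size
selection, cross-platform signature transfer, and ROC/Youden diagnostic
evaluation.

The package is aimed at analysts building binary tissue classifiers from
small bulk-microarray cohorts (the motivating case is idiopathic pulmonary
fibrosis, IPF, versus normal lung), where a signature trained on one
platform must be validated on an independent cohort measured on another.

## The model

Given a log2 expression matrix (features x samples) and binary phenotype
labels `y`, training proceeds as:

1. **Panel selection.** Features are ranked by the pooled two-sample
   Student t statistic and the top *k* form the signature panel.
2. **Metagene factors.** The k x n panel submatrix is standardized per
   feature (training mean/SD) and decomposed, `X = U S Vᵀ`. The first
   *r* = 2 right singular vectors are the per-sample factor scores; a new
   standardized profile `x` is projected as `f = S⁻¹ Uᵀ x`.
3. **Bayesian probit regression.** `Pr(y = 1) = Φ(β₀ + fᵀβ)` with prior
   `β ~ N(0, diag(100, 4, 4))`, sampled by Albert–Chib latent-variable
   Gibbs sampling (truncated-normal latents, conjugate Gaussian update).
   The predicted probability is the posterior mean of `Φ(β₀ + fᵀβ)` over
   the retained draws.
4. **Model size.** *k* is chosen by leave-one-out cross-validation:
   for each candidate size the whole procedure (ranking, standardization,
   SVD, fit) is re-run on every fold and the smallest *k* minimizing the
   sum of deviances `Σ −2[y log p + (1−y) log(1−p)]` is kept.
5. **Cross-platform transfer.** Validation features are mapped many-by-many
   to training features through shared gene identifiers (averaging multiple
   partners), scale/shift normalized per feature to the training moments,
   and projected through the *training-only* SVD loadings (least squares on
   the available loading rows), so validation predictions are independent
   of validation labels.
6. **Evaluation.** ROC/AUC (Mann–Whitney concordance), the Youden-index
   operating point, sensitivity/specificity/PPV/NPV/accuracy, and a
   Wilcoxon rank-sum association test.

A seeded synthetic-cohort generator (`simulateCohort`,
`simulateSecondPlatform`) reproduces the data structure this workflow
assumes — paired upper/lower lobe samples sharing a patient effect, a
biopsy/explant batch split within cases, and a second platform related to
the first by a many-by-many feature map with per-feature affine distortion
— so every stage is testable without external downloads.

## Worked example

```r
library(bprsig)

## cohort summary layer on the bundled clinical table
ph <- readPhenotypeTable(system.file("extdata", "table1_cohort.tsv",
                                     package = "bprsig"))
s <- summarizeCohort(ph[ph$phenotype == 1, ], "sample_type", c("age", "sex"))
round(c(s$biopsy$age$mean, s$biopsy$age$se), 2)
#> [1] 60.67  2.72
round(c(s$explant$age$mean, s$explant$age$se), 2)
#> [1] 66.60  0.68

## end-to-end synthetic run: simulate, preprocess, tune, train, transfer
cfg <- makeDemoConfig("tiny", seed = 11)
res <- runPipeline(cfg, "demo_run")
res$report
#> ValidationReport: 31 cases / 15 controls
#>   AUC 0.806 | Youden cutoff 0.630 (J = 0.604)
#>   sens 87% spec 73% PPV 87% NPV 73% accuracy 83% | Wilcoxon p = 0.000877
```

The report reads: on a 31-case/15-control synthetic validation cohort
measured on a distorted second platform, the transferred two-factor
signature separates cases from controls with AUC 0.806; at the cutoff
maximizing sensitivity + specificity it calls 87% of cases and 73% of
controls correctly, and the rank-sum test confirms the association
(p < 0.001). `demo_run/` holds the dendrogram (Newick), the model-size
trace, the serialized model and a manifest that reproduces the run
bit-for-bit.

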