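# sssHD — stable sparse feature selection for class-imbalanced data

High-dimensional binary data with a rare positive class — tumour subtypes
against a large control pool, a minority phenotype among thousands of gene
expression profiles — defeats accuracy-driven feature selection: the
majority class dominates the criterion and the classifier's continuous
output shifts toward the minority as the imbalance grows. `sssHD` selects
features with a criterion immune to both effects: the **Hellinger
distance** between the decision-score distributions of the two classes.

Under binormality the squared Hellinger distance between the class score
distributions has the closed form

    D_H^2 = 2 - 2 * sqrt(2*s1*s0 / (s1^2 + s0^2)) * exp(-(m1 - m0)^2 / (4*(s1^2 + s0^2)))

which depends only on per-class means and variances — it is
**skew-insensitive** (class priors never enter) and
**translation-invariant** (a shifted decision boundary changes nothing).
The sssHD algorithm embeds this criterion in a sparse classifier:

1. fit an elastic-net penalized linear SVM
   (`hinge + lambda * (0.5*(1-alpha)*||b||_2^2 + alpha*||b||_1)`)
   over a `(lambda, alpha)` grid (coordinate descent in C++);
2. score every grid point by the Hellinger distance between class-split
   **out-of-fold** decision scores (stratified k-fold), and keep the most
   parsimonious model within one standard error of the best;
3. repeat on stratified subsamples that preserve the imbalance ratio and
   rank features by their **inclusion frequency**
   `f_j = (1/K) * sum_k 1{beta_j^(k) != 0}`.

The package also ships the comparison baselines (Fisher score, Relief,
per-feature AUCROC/AUCPRC filters, accuracy- and AUC-tuned SVMs),
imbalance-aware metrics (G-mean, F-measure, lower-trapezoid AUCROC,
PR curves), SMOTE oversampling, stratified splitting protocols, and the
blocked-covariance Gaussian simulation harness used to benchmark the
criteria.

## Worked example

A 9:1 imbalanced dataset with 200 samples, 100 correlated features, of
which the first 10 carry a class-mean shift of 2:

```r
library(sssHD)
s <- scenario(p = 100, rho = 0.4, n0 = 180, n1 = 20)
d <- generate_data(s, seed = 42)

res <- stability_select(d$X, d$y,
                        grid = ssshd_grid(alphas = c(0.5, 1), nlambda = 10),
                        K = 20, fraction = 0.5, seed = 42)
res
#> sssHD stability selection: 20 runs, per-class fraction 0.5
#>   top features: V2 (f=1.0), V7 (f=0.9), V4 (f=0.8), V6 (f=0.8), V8 (f=0.8)

sort(select_top_q(res, 10))
#>  [1]  1  2  3  4  5  6  7  8 10 77
evaluate_selection(select_top_q(res, 10), s)
#> C = 9, IC = 1, FDR = 0.10
```

Nine of the ten top-ranked features are true signal features despite the
9:1 skew (`imbalance_ratio(d$y)` is 9.00); the inclusion frequency of a
feature is the fraction of the 20 subsampling runs in which its SVM
coefficient was nonzero. A single HD-tuned fit shows what the criterion
selects before stabilization:

```r
tw <- tune_by_hd(d$X, d$y, seed = 1,
                 grid = ssshd_grid(alphas = c(0.5, 1), nlambda = 10))
#> lambda = 8.771, alpha = 1.00, 12 nonzero coefficients, held-out HD = 1.274
```

The held-out HD of 1.274 is the average out-of-fold Hellinger distance
(bounded by sqrt(2) ~ 1.414) between the two classes' score
distributions at the winning grid point.

For delimited text data, `read_dataset()` + `run_selection_workflow()`
(or the `inst/cli/ssshd` command-line tool with subcommands `select`,
`simulate`, `evaluate`, `smote`) run the same pipeline end to end and
write ranking/metrics TSVs plus a reproducibility manifest.

## The simulation benchmark

`run_table1()` compares the HD criterion with accuracy- and AUC-based
tuning on identical fits, reporting mean counts of correctly (C, out of
10) and incorrectly (IC) selected features and the FDR:

```r
run_table1(scenario(p = 100, rho = 0, n0 = 864, n1 = 96),
           reps = 50, seed = 1)   # 9:1 imbalance
```

Across imbalance ratios the HD column stays at C ~ 10 with IC ~ 0 while
the accuracy criterion's false discoveries grow with the skew — the
pattern that motivates the method.

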