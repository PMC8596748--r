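# abdetect

Simulation and automated effect detection for single-case AB graphs.

Behavior analysts and n-of-1 trialists decide whether a treatment changed
behavior by inspecting a two-phase (baseline A, treatment B) graph. Visual
inspection is the norm but raters disagree, and agreement alone says nothing
about validity — whether a judged change corresponds to a *true* effect.
`abdetect` provides the machinery to study that question: a simulator that
produces AB graphs with known ground truth, three automated detectors, and a
harness that scores any decision vector (a method's or a human rater's) by
accuracy, Type I error rate, and power.

## What it implements

**Simulator.** Each graph is an AR(1) series
`x_t = a·x_{t−1} + e_t`, `e_t ~ N(0,1)`, optionally sheared by a 30° trend
(`tan 30° ≈ 0.58` per session about the series midpoint), shifted by a level
constant (+10 stable, +4 variable — variability coefficients 0.1 / 0.25),
with a standardized mean difference (SMD 0–5, in baseline-SD units) added to
Phase B. `ab_test_set()` builds the counterbalanced 1,024-graph evaluation
set (12 no-effect + 4-per-SMD graphs in each of the 32 combinations of
phase lengths 3/5 and 5/10, autocorrelation 0/0.2, trend 0/30°,
stable/variable); `ab_training_set()` builds the class-balanced 96,000-graph
training scheme (300 graphs per combination × positive-SMD cell).

**Detectors.**

* `cdc_classify()` — the conservative dual-criteria rule: project the
  Phase A mean and OLS trend lines over Phase B, raise both by
  0.25 × SD(Phase A), count B points above both; effect at ≥ 5/5 or ≥ 8/10.
* `train_sgd()` — a linear classifier fit by stochastic gradient descent on
  the regularized hinge loss (compiled inner loop, seed-reproducible).
* `train_svc()` — an RBF-kernel support vector classifier (cost 1,
  γ = 1/(8·Var(X))), optionally on a class- and cell-balanced subsample.

Both classifiers consume 8 features per graph (`extract_features()`):
per-phase means, SDs, and OLS intercepts/slopes of the per-graph
standardized series — a representation invariant to the level/variability
manipulation by construction.

**Harness.** `accuracy()`, `type1_rate()`, `power_rate()`,
`agreement_matrix()`, `stratify_metrics()` (per characteristic, with the
Type-I-at-SMD-0 / power-at-SMD-1..5 layout), Wald `binomial_ci()`, and the
point-versus-interval `significance_flag()`. CSV vector I/O matches the
flat one-decision-per-line layout used for rater files, and
`render_graphs()` writes one-graph-per-page PDFs for blind rating.

## Worked example

```r
library(abdetect)

train <- ab_training_set(seed = 42, total = 3200)  # small demo run
test  <- ab_test_set(seed = 7)
truth <- manifest_truth(test)

cdc <- cdc_batch(test)
x_train <- feature_matrix(train)
sgd <- train_sgd(x_train, manifest_truth(train), seed = 1)
svc <- train_svc(x_train, manifest_truth(train), seed = 1)
x_test <- feature_matrix(test)
preds <- list(CDC = cdc, SGD = predict(sgd, x_test), SVC = predict(svc, x_test))

round(agreement_matrix(preds, truth = truth), 2)
#>      True  CDC  SGD  SVC
#> True 1.00 0.74 0.83 0.83
#> CDC  0.74 1.00 0.80 0.80
#> SGD  0.83 0.80 1.00 0.90
#> SVC  0.83 0.80 0.90 1.00
```

The first column is each method's accuracy against the ground truth: the
CDC rule gets 74% of the 1,024 graphs right, both classifiers 83%, and the
two classifiers agree with each other on 90% — even this 3,200-graph
training run separates the methods cleanly. A full report for one method:

```r
metrics_report(preds$SVC, truth, manifest = test, method = "SVC")
#> <metrics_report> method "SVC"
#>   accuracy 0.832 [0.809, 0.855] (n = 1024)
#>   type1    0.096 [0.067, 0.126] (n = 384)
#>   power    0.789 [0.757, 0.821] (n = 640)
#>   + stratified rows: 36
```

So the SVC falsely flags 9.6% of no-effect graphs and detects 78.9% of true
effects; brackets are 95% Wald intervals. The SMD stratum of the report
shows the power curve: .41 at SMD 1, .67 at 2, .88 at 3, .98 at 4, 1.00
at 5 — small effects hide in the unit-SD noise, effects of 3+ SD are nearly
always caught.

A command-line wrapper over the same functions ships at
`inst/cli/abdetect` (`simulate`, `apply-cdc`, `train`, `predict`,
`evaluate`, `render`), e.g.

```sh
Rscript inst/cli/abdetect simulate --scheme test_1024 --seed 7 \
    --out test.csv --truth-out truth.csv --verbose
Rscript inst/cli/abdetect apply-cdc --manifest test.csv --out cdc.csv
Rscript inst/cli/abdetect evaluate --truth truth.csv --pred cdc=cdc.csv \
    --manifest test.csv --out report.csv
```

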