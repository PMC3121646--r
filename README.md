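# pincom

Calibrating, comparing and combining heterogeneous multi-class
classifiers by precision.

## The problem

Probabilistic classifiers built from different learning algorithms —
random forests, support vector machines, neural networks, nearest
neighbours — all report posterior class-membership probabilities, but
those probabilities live on incompatible scales.  The maximum posterior
MaxP(x) = max_c p(c|x) ranks predictions *within* one model, yet a MaxP
of 0.6 from an SVM and 0.6 from a neural network say nothing comparable
about reliability.  In gene-function classification from expression
profiles — many small classes, noisy data, each algorithm good at
different classes — this blocks the obvious move of letting the models
cooperate.

`pincom` implements the precision-index framework for this situation:

* **PIN** (precision index): for each model, the observed tail precision
  Pindex(a) = precision of {MaxP ≥ a} is regressed isotonically on MaxP
  (weighted pool-adjacent-violators, one knot per distinct MaxP,
  weight = tie count) and interpolated linearly.  PIN is a precision, so
  it is directly comparable across arbitrary models.
* **PINCom**: the combined classifier that assigns each instance the
  predicted class of whichever model has the highest PIN for it; its
  confidence score is MaxPIN = max_i PIN^{M_i}(x).
* **PIC** (class-specific precision index): the same tail-precision
  construction restricted to the predictions of one class, as a function
  of PIN — the tool for extracting small prediction sets with precision
  beyond the overall curve's maximum.
* **Recall–precision curves** with monotone smoothing and threshold
  inversion (`threshold_for_precision()`, `threshold_for_recall()`).
* **Validation protocols**: repeated cross-validation for fitting PIN
  functions, application to test data, and leakage-free double
  cross-validation for honest evaluation, plus precision/recall
  estimation for unlabeled test sets.
* **Baselines**: plurality vote, multi-response linear-regression
  stacking, random-forest stacking, and a leave-one-classifier-out
  contribution analysis.
* **Synthetic benchmark**: a Gaussian-mixture generator with an exact
  Bayes-posterior oracle and engineered complementary "expert"
  pseudo-models.

## Worked example

Two pseudo-classifiers, each exactly calibrated on half of the classes
of a 6-class Gaussian mixture and noise-degraded on the other half,
combined by maximum PIN:

```r
library(pincom)

cfg <- mixture_config(C = 6, sizes = rep(100, 6), d = 8,
                      separability = 2.5, seed = 1)
d <- generate_mixture(cfg)
experts <- make_expert_models(cfg,
                              list(e1 = cfg$classes[1:3],
                                   e2 = cfg$classes[4:6]),
                              noise = 0.85, seed = 2)
truth <- setNames(d$labels, d$instance_ids)
recs <- lapply(experts, function(gen) {
  r <- maxp_and_class(gen(d), truth)   # predicted class + MaxP
  add_pin(r, fit_pin(r))               # calibrate MaxP -> PIN
})
com <- combine_pin(recs, seed = 3)     # follow the per-instance PIN leader

prec <- function(r) mean(r$predicted_class == r$true_class)
round(c(expert1 = prec(recs$e1), expert2 = prec(recs$e2),
        pincom = prec(com)), 3)
#> expert1 expert2  pincom
#>    0.51    0.58    0.74
```

Each expert classifies barely over half the instances correctly
(good on its own classes, near chance elsewhere); the combination, by
following whichever model is more reliable per instance, reaches 74%.
The combined confidence score supports precision-targeted selection:

```r
cv <- rp_curve(com, "max_pin")
cv
#> <rp_curve> score max_pin: 182 thresholds, overall P(0) = R(0) = 0.7393,
#>            max smoothed precision 1
threshold_for_precision(cv, 0.9)
#> $threshold   0.9
#> $precision   0.9
#> $recall      0.568
#> $subset_size 378
```

i.e. 378 of the 600 predictions can be kept at 90% precision,
capturing 56.8% of all correct predictions.

For real tabular data the flow is the same with trained learners:
build `classifier_spec()`s (`"rf"`, `"svm"`, `"nn"`, `"knn"`, `"lda"`,
`"multinom"`, or anything added via `register_learner()`), fit PIN
functions on cross-validated predictions with `cv_level0()` +
`estimate_pins_A1()`, apply them to new data with `apply_A2()`, and
evaluate honestly with `double_cv()`.  A thin command-line wrapper with
`simulate` / `train` / `predict` / `evaluate` / `combine` / `report`
subcommands is installed at `system.file("cli", "pincom",
package = "pincom")`.

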