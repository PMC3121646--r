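---
title: "Calibrating and combining heterogeneous classifiers with the precision index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating and combining heterogeneous classifiers with the precision index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pincom)
```

## The problem

Multi-class probabilistic classifiers report, for each instance $x$, a
vector of posterior class-membership probabilities $p(c \mid x)$ and the
decision $\hat y(x) = \arg\max_c p(c \mid x)$.  The maximum posterior,

$$\mathrm{MaxP}(x) = \max_c \, p(c \mid x),$$

is each model's natural confidence score, and within one model a higher
MaxP does generally signal a more reliable prediction.  Across models it
does not: a random forest's vote fractions, an SVM's pairwise-coupled
probabilities and a neural network's softmax outputs live on different,
incompatible scales.  A MaxP of 0.6 from one learner may carry the
empirical reliability of 0.9 from another.  That makes it impossible to
say which of two models' predictions for the same gene is more
trustworthy, and impossible to combine very different learners by
comparing their confidences directly.

This matters most in settings like gene-function classification from
expression profiles: many classes of very unequal size, noisy data,
modest overall accuracy, and the repeated observation that different
learning algorithms excel on *different* classes, so that discarding all
but one model throws information away.

## The precision index (PIN)

The fix is to re-express each model's confidence on a scale that means
the same thing for every model: observed precision.  For a scored set of
predictions with known truth, define the tail precision at threshold
$a$,

$$\mathrm{Pindex}(a) \;=\;
\frac{\#\{i : \mathrm{MaxP}(x_i) \ge a,\ \hat y(x_i) = y_i\}}
     {\#\{i : \mathrm{MaxP}(x_i) \ge a\}},$$

the fraction correct among all predictions at least as confident as $a$.
Each record inherits the value at its own confidence,
$\mathrm{Pindex}(x_i) = \mathrm{Pindex}(\mathrm{MaxP}(x_i))$; records
with tied MaxP share one value, because Pindex is a function of the
threshold, not of the record.

If MaxP is informative at all, tail precision should not decrease as the
threshold rises, but the empirical values fluctuate.  The **precision
index** PIN is the monotone non-decreasing calibration obtained by
isotonic regression of the observed Pindex values on MaxP:

* one knot per distinct MaxP value, with weight equal to the number of
  tied records;
* weighted least-squares isotonic fit by the pool-adjacent-violators
  algorithm (`pava_fit()`), which replaces each violating run by its
  weighted mean and provably minimizes the weighted squared error over
  all monotone vectors;
* linear interpolation between knots and clamping to the endpoint values
  outside the observed range (`predict.pin_function()`).

Where MaxP is locally uninformative the fit is constant, which is
exactly the right statement: in that region the model cannot rank its
own predictions.  Because PIN is a precision, PIN values from arbitrary
models are directly comparable.

Two deliberate choices deserve note.  First, the regression target is
the observed tail precision itself, not the 0/1 correctness indicator;
the two differ in how records are weighted, and the tail-precision form
is the definition implemented throughout.  Second, the isotonic loss is
squared error, and ties in MaxP are pooled before fitting.

## The combined classifier (PINCom)

Given models $M_1, \dots, M_L$ with calibrated indices
$\mathrm{PIN}^{M_i}(x)$, the combined classifier assigns each instance
the predicted class of whichever model is most reliable *for that
instance*:

$$\hat y^{C}(x) = \hat y^{M_{i^*}}(x), \qquad
  i^* = \arg\max_i \mathrm{PIN}^{M_i}(x),$$

and its own confidence score is
$\mathrm{MaxPIN}(x) = \max_i \mathrm{PIN}^{M_i}(x)$.  Ties in PIN are
resolved uniformly at random from a dedicated seeded stream
(`combine_pin()`), so the combination is reproducible independently of
the learners' own randomness.  MaxPIN plays the role of MaxP for the
combined classifier and feeds the same curve machinery.

The point of the construction is complementarity: when different models
dominate different classes, following the per-instance PIN leader yields
higher precision *and* more high-confidence predictions than any single
model.  The package's synthetic expert scenario
(`make_expert_models()`) makes this testable: two pseudo-models, each
exactly Bayes-calibrated on half the classes and noise-degraded
elsewhere, combine into a classifier strictly better than either.

## Recall-precision curves and threshold inversion

For any confidence score $s$ (MaxP, PIN, MaxPIN or PIC), `rp_curve()`
tracks over thresholds $a$

$$P(a) = \text{precision of } \{s \ge a\}, \qquad
  R(a) = \frac{\#\{\text{correct in } s \ge a\}}{n},$$

with $P(0) = R(0)$ equal to the overall precision.  The raw step curves
are retained for diagnostics; for analysis, $P$ is smoothed isotonically
(non-decreasing) and $R$ antitonically (non-increasing), each with tie
multiplicities as weights and linear interpolation in between.

`threshold_for_precision()` returns the *smallest* threshold whose
smoothed precision reaches a target $P_0$ — i.e. the largest prediction
set with that precision — along with the recall and subset size;
`threshold_for_recall()` is the mirror operation.  A target above the
curve's maximum raises an "unreachable precision" error that reports the
achievable maximum, a real phenomenon: the overall curve of a combined
classifier frequently tops out well below 100%.

## Class-specific precision (PIC)

The overall curve can top out at a moderate precision while individual
classes are predicted almost perfectly.  The **class-specific precision
index** repeats the tail-precision construction inside each predicted
class, as a function of PIN:

$$P_k(a) = \text{precision of } \{\mathrm{PIN}(x) \ge a,\ \hat y(x) = k\},
\qquad \mathrm{PIC}(x) = P_k(\mathrm{PIN}(x)).$$

PIC values spread wider and reach higher than PIN, so thresholding on
PIC is the tool for selecting small, very-high-precision prediction
sets that the overall curve cannot deliver.  Two guard rails apply
(`fit_pic()`):

* classes with fewer than 3 predictions get a constant PIC equal to the
  class precision — an isotonic fit on 1–2 points is vacuous;
* a class never predicted in the calibration records has no curve; at
  evaluation time the record's PIN is returned unchanged, with a
  warning.  This is conservative: it neither invents class-level
  precision nor discards the record.

## Fitting PIN without self-calibration: the protocols

PIN functions must be fitted on predictions whose correctness is not
contaminated by the fit itself.  The package implements the two-stage
protocol:

**Stage A (deployment).**  `cv_level0()` repeats a random
`n_folds`-fold partition `K` times; each model is trained on the
complement of each fold and predicts the held-out fold, giving
$K \times n$ cross-validated records per model, all models sharing
identical partitions (paired design).  `estimate_pins_A1()` fits one
PIN function per model on its pooled records and forms the combined
training predictions.  `apply_A2()` then refits every model on the full
training set, predicts the test set, maps test MaxP through the
training-fitted PIN functions, and combines by maximum PIN.

**Stage B (honest evaluation).**  When no labeled test set exists, the
combined classifier must be evaluated without letting any instance
influence its own calibration.  `double_cv()` nests the whole of stage
A inside an outer cross-validation: for each outer fold, an inner
`K`-repeat CV on the remaining ~90% fits the PIN functions (so roughly
81% of the data trains and 9% calibrates at any moment); models trained
on the 90% then predict the outer 10%, the *inner* PIN functions are
applied, and the maximum-PIN combination is formed.  The full pass
repeats `KK` times, yielding $KK \times n$ double-cross-validated
records.  An audit trail records, per (pass, outer fold), exactly which
instances entered the inner fits; the tests assert the intersection
with the outer fold is empty.

**Unlabeled test sets.**  `estimate_test_pr()` transfers double-CV
precision to an unlabeled test set: the subset $\{s \ge a\}$ of test
predictions is credited $|\{s \ge a\}| \times P_{xv}(a)$ estimated
correct predictions, where $P_{xv}$ is the double-CV precision curve;
with PIC thresholding the estimate is formed per predicted class with
the class-specific curves and summed.  Defaults follow the protocol
design: 10 folds, `K = 20` repeats for PIN fitting (20–50 is the
sensible range), `KK = 10` double-CV passes.  The examples and tests in
this package use smaller `K`/`KK` with fast learners (LDA,
vote-fraction kNN) so a full run takes seconds; the protocol scales
linearly in `K × KK × n_folds` model fits, and `double_cv()` warns when
the estimated fit count is large.

## Baselines

Two standard fusion baselines ship for comparison, consuming the *same*
cross-validated level-0 outputs as the PIN machinery so comparisons are
paired:

* **Vote** (`vote_combine()`): plurality class, ties broken by a seeded
  uniform draw.
* **Stack 1** (`stack1_fit()`): multi-response linear regression — one
  plain least-squares regression of each class's 0/1 indicator on all
  $L \times C$ level-0 class probabilities, prediction by argmax of the
  fitted responses.  No regularization is applied, deliberately: the
  vanilla behavior (including its tendency to overfit when
  $L \times C$ approaches the number of training records) is the
  reference point.  Probability blocks sum to 1 per row, so the design
  is rank-deficient with an intercept; the fit uses the minimal-norm
  least-squares solution and warns.
* **Stack 2** (`stack2_fit()`): a random forest on the $L \times C$
  probabilities plus the $L$ predicted-class columns.  The predicted
  classes are supplied as factor columns, which the forest splits on
  natively — equivalent in expressive power to a one-hot encoding and
  the idiomatic choice for R forests; the level-1 width is
  $L \times C + L$ columns.

`contribution_analysis()` quantifies each model's value to the
combination: the recall of the full $L$-model combination at a target
precision minus the recall of the combination rebuilt without that
model.  Negative entries are meaningful — a model can hurt.

## The synthetic benchmark

`mixture_config()` / `generate_mixture()` produce the statistical
setting the method assumes, not a simulation of biology: $C$ spherical
Gaussian classes $N(\mu_k, \sigma^2 I_d)$ with fixed per-class counts
and heterogeneous separability (mean norms ramping from 1 to 3 by
default).  Defaults emulate a gene-function training table: 21 classes
with sizes 8–50 (367 instances), 60 features.  Deterministic per-class
counts (not multinomial draws) keep bookkeeping invariants exact, and
the shared spherical covariance keeps the Bayes posterior closed-form
(`bayes_posterior()`), providing an *exactly calibrated* reference
classifier for the calibration tests: its MaxP is the true probability
that its prediction is correct.

What the generator does **not** emulate: correlated features, heavy
tails, batch structure, label noise, and multi-label classes — all
present in real expression data.  Passing tests therefore demonstrate
the method's internal correctness and its behavior under its own
assumptions, not performance on any real dataset.

## Numerical choices and edge cases

* Posterior rows are clipped to $[10^{-12}, 1]$ and renormalized before
  MaxP extraction, guarding learners that emit exact zeros.
* Argmax ties take the lowest class-vocabulary index, deterministically.
* PIN/PIC evaluation clamps outside the fitted knot range; a fit on a
  single distinct score value is the constant overall precision.
* Folds are stratified by class by default: with classes of 8 instances,
  a fully random 10-fold split can strand a class outside a training
  fold.  `stratified = FALSE` restores literal random partitions.
* Oversampling (`oversample()`) duplicates whole copies of each smaller
  class and tops up with the class's first instances in original order,
  so the result is exactly balanced and the operation idempotent.
  Duplicates are exact copies, not jittered.
* One master seed derives independent streams (via `derive_seed()`) for
  partitioning, learner fits and tie-breaks, so each component is
  reproducible in isolation.

## Known limitations

* The empirical smoothed precision curve of a *continuous* score keeps
  the raw value of its extreme top knot (a single record's 0/1
  correctness), so the top end of any curve built from few records has
  high variance.  Tied scores pool into well-estimated knots; for
  near-noise scores the flattening of the curve is only guaranteed in
  that tied regime.  Practical reading: do not over-interpret the last
  few points of any recall-precision curve.
* PIC fitted and evaluated on the same records is optimistic; use the
  double-CV records for calibration, as stage B does.
* Built-in learners cover random forest, radial SVM, softmax neural
  network, vote-fraction kNN, LDA and multinomial regression.  A MARS
  learner is not bundled, but any learner can be added through
  `register_learner()` with the same contract.
* Multi-label (multi-function) classification is out of scope; each
  instance carries one primary class.

## A compact worked example

```{r example}
cfg <- mixture_config(C = 6, sizes = rep(100, 6), d = 8,
                      separability = 2.5, seed = 1)
d <- generate_mixture(cfg)
experts <- make_expert_models(cfg,
                              list(e1 = cfg$classes[1:3],
                                   e2 = cfg$classes[4:6]),
                              noise = 0.85, seed = 2)
truth <- setNames(d$labels, d$instance_ids)
recs <- lapply(experts, function(gen) {
  r <- maxp_and_class(gen(d), truth)
  add_pin(r, fit_pin(r))
})
com <- combine_pin(recs, seed = 3)
prec <- function(r) mean(r$predicted_class == r$true_class)
c(expert1 = prec(recs$e1), expert2 = prec(recs$e2),
  pincom = prec(com))
```

Each expert is mediocre overall; the maximum-PIN combination recovers
most of what either knows, on every class.
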