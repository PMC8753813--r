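---
title: "Orthogonal-array hyperparameter screening and majority-vote ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal-array hyperparameter screening and majority-vote ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oaensemble)
```

## The problem

Distinguishing acute lymphoblastic leukemia (ALL) blast cells from
normal lymphocytes in single-cell microscopy images is a binary
classification task in which the two classes are morphologically very
similar: blasts tend to have larger nuclei with more irregular
boundaries, but the overlap is substantial. Deep classifiers fine-tuned
on such data are sensitive to their *training* hyperparameters —
optimizer, mini-batch size, number of epochs, initial learning rate —
and a full grid over even three candidate values per hyperparameter
needs $3^4 = 81$ training runs. This package implements two
complementary ideas for that setting:

1. a **Taguchi orthogonal-array screen** that estimates the best of the
   81 combinations from only nine training experiments, and
2. a **majority-voting ensemble** of independently trained classifiers
   at the selected combination, evaluated with confusion-matrix metrics
   and a per-image error profile.

Everything runs at desk scale: a synthetic cell-image generator and two
reference trainer backends stand in for GPU-scale fine-tuning, while the
statistics themselves are exact and are exercised against the published
tables of a real ALL screening study that ship as fixtures.

## The screening model

The design is the standard $L_9(3^4)$ orthogonal array (`l9_oa()`):
nine rows, four columns, each column balanced over the three levels, and
every pair of columns realising all nine ordered level pairs exactly
once. Level indices are 1-based throughout, matching how such designs
are printed. The array is hard-coded and validated
(`validate_orthogonality()`) rather than generated: the workflow uses
exactly this one design, and a general orthogonal-array constructor
would add surface without adding capability.

Each experiment $i$ is run $n$ times (default 3) and its run accuracies
$y_t \in [0,1]$ are collapsed into the smaller-the-better
signal-to-noise ratio

$$\eta_i = -10 \log_{10} (\bar y_i - m)^2, \qquad
  \bar y_i = \tfrac1n \sum_t y_t,$$

with target $m = 1$ (100% accuracy): the quantity driven to zero is the
mean error rate, so larger $\eta$ (in dB) means accuracy closer to 1.
Two conventions here are deliberate and verified numerically rather than
assumed: the logarithm is base 10 (only base 10 reproduces the reference
tables, e.g. $\eta = 33.4870$ dB from $\bar y = 0.97883$), and the
standard deviation reported alongside is the *sample* SD with the $n-1$
denominator (the only convention reproducing the printed 0.0010 and
0.0136). A mean accuracy exactly equal to $m$ makes $\eta$ undefined;
`summarize_runs()` treats this as a hard error rather than clamping,
because silently capping a degenerate SNR would corrupt every downstream
average. (The confirmation-run summary is the one place a perfect score
can legitimately occur at desk scale, and there it is reported as `NA`
with a warning instead.)

The fitted object returned by `taguchi()` contains:

* the **response table** $E_{fl}$, the mean of the three $\eta_i$ whose
  design row has factor $f$ at level $l$; the factor *effect* is
  $\max_l E_{fl} - \min_l E_{fl}$ and the best level is
  $\arg\max_l E_{fl}$. Duplicate level *values* (the reference study's
  optimizer factor lists `adam, sgdm, adam`) are kept as distinct design
  levels, because the response table and ANOVA distinguish them. Ties
  for the best level cannot arise from continuous accuracy data; if one
  is constructed, the lowest level index wins and a warning is emitted.
* the **Taguchi ANOVA**: $SS_f = 3\sum_l (E_{fl}-\bar\eta)^2$ with 2 df
  per three-level factor, against the total
  $S_T = \sum_i (\eta_i - \bar\eta)^2$ with 8 df. Four three-level
  factors exhaust all 8 df, so the residual error SS and df are both
  zero; the expected sum of squares $SS_f - df_f\,V_{error}$ then equals
  $SS_f$, and the percentage contribution is $SS_f / S_T \times 100$.
  The printed ANOVA flags this (`Error df = 0`) because with a smaller
  design the pooling rule would matter. The identity
  $\sum_f SS_f = S_T$ is asserted to $10^{-9}$ relative tolerance in the
  tests.
* an **additive main-effects predictor**
  ($\hat\eta = \bar\eta + \sum_f (E_{f,l_f} - \bar\eta)$, the usual
  Taguchi prediction equation) exposed through `predict()`, `fitted()`
  and `residuals()`.

The response table and ANOVA are computed from the *preliminary-test*
$\eta$ values by default, not the training-set ones: generalisation
accuracy is the quality characteristic being optimised, and that is the
choice that reproduces the bundled reference tables. The API accepts any
split label.

```{r taguchi}
fit <- taguchi(read_runs_csv(example_table("screening_runs")),
               space = read_factor_space(example_table("factors")))
summary(fit)
```

## The ensemble model

`majority_vote()` assigns each image the label predicted by strictly
more than half of the member models. The positive class is `ALL`
throughout. Confusion matrices use the predicted-rows by actual-columns
layout, and `classification_metrics()` reports accuracy, precision
(positive predictive value), recall (sensitivity), specificity
(true-negative rate) and $F_1 = 2PR/(P+R)$. Undefined ratios (zero
denominator) are `NaN` with a warning rather than silently 0 or 1.

Design choices worth recording:

* **Even member counts** can tie; a tie breaks toward `ALL` with a
  warning. In a screening context a false positive costs a review while
  a false negative costs a missed diagnosis, so the tie favours recall.
  The canonical workflow only uses odd sizes, where ties are impossible.
* **Nested ensembles** of size $k$ vote over the *first* $k$ models in
  confirmation-run order, so `ensemble-3` ⊂ `ensemble-5` ⊂ … ⊂
  `ensemble-9`, mirroring how growing committees are usually compared.
* `error_profile()` records, for every image the ensemble misclassifies,
  how many individual members also got it wrong. Because the ensemble
  only errs when a strict majority errs, every multiplicity is at least
  $\lceil k/2 \rceil$; bucket totals per actual class must equal the
  ensemble's FN (actual `ALL`) and FP (actual `Normal`) counts, an
  identity the tests assert.

## Trainer backends

The trainer contract (`train_model()` + `predict()`) is deliberately
small so that a GPU-scale transfer-learning backend can be plugged in
unchanged: a backend receives a hyperparameter combination, a labeled
image set with `train` / `preliminary_test` splits, and a seed, and
must return a handle with deterministic predictions and recorded
accuracies. Two reference backends ship with the package:

* **`surrogate_backend()`** — a closed-form objective
  (`base + additive level effects + a small A×B interaction + seeded
  noise`) with no training at all. It serves three purposes: exhaustive
  oracle tests (the full 81-combination grid can be brute-forced with
  `surrogate_grid()`), injection of recorded accuracy tables so the
  Taguchi statistics can be driven from a printed table, and fast
  pipeline smoke runs. `random_surrogate()` draws seeded instances with
  main-effect SD 0.05, interaction SD 0.01 and run noise SD 0.005 —
  effects an order of magnitude above the noise, which is the regime a
  screening design is intended for.
* **`tiny_cnn_backend()`** — a small convolutional classifier written in
  base R: a bank of eight fixed, seeded, zero-mean 5×5 random filters on
  the 32×32 grey image, ReLU, 7×7 block average pooling (128 features),
  then a logistic-regression head on standardised features trained by
  mini-batch gradient descent. The head honours all four screened
  hyperparameters — `adam` (adaptive moments) vs `sgdm` (momentum 0.9,
  a conventional value the screen does not vary), mini-batch size,
  epochs, and the initial learning rate used as a constant step size.
  The frozen-feature/trainable-head split is the same shape as a
  transfer-learning workflow, at a size that trains in well under a
  second per model on one CPU.

Seed policy: every public entry point takes one master seed and expands
it deterministically (`sample.int` under the master seed) into
per-experiment × per-run seeds, so whole pipelines are bit-reproducible
and the library never disturbs the caller's RNG state.

## Synthetic cell images

`synthetic_cells()` renders single-cell images on a noisy bright
background. The nucleus is a filled region bounded by the radial
function $r(\theta) = r_0 (1 + \sum_k a_k \sin(k\theta + \phi_k))$:
`Normal` cells get a smaller $r_0$ and three low-order, low-amplitude
harmonics (round, smooth boundary); `ALL` cells get $r_0$ larger by up
to 30% and more, larger, higher-order harmonics (irregular boundary),
both gaps scaled by a `separability` parameter in $[0,1]$. At
separability 0 the two classes are drawn from the identical
distribution, which pins the false-discovery side of every downstream
test: a two-feature threshold classifier (nucleus area + boundary
roughness, measured with EBImage) must sit at chance there, and reaches
≥ 0.95 accuracy at separability 1. Default image size is 128 pixels
(test default 32–64 for speed); `preprocess_images()` resizes
bilinearly when a backend wants its own input size, replicating
greyscale inputs to three channels.

What the generator emulates is the *morphology contrast* (size and
boundary irregularity) and the class balance/split structure of a
two-class single-cell dataset. What it does not emulate: staining
variation, multi-cell scenes, focus artefacts, label noise, or the
class imbalance of real screening data. Passing tests on synthetic
cells therefore validate the *workflow* — design, SNR arithmetic,
voting, error accounting — not the absolute accuracy a fine-tuned deep
network would reach on a real microscopy corpus; the exact-arithmetic
fixtures cover the latter's recorded statistics instead.

## Problem sizes and numerical choices

The suite and the acceptance script choose sizes that keep every run
deterministic and fast while leaving the conclusions meaningful: the
surrogate-oracle property uses 20 seeded instances × 27 training calls
against the 81-combination brute force; the tiny-CNN smoke runs use 400
training / 100 test images at separability 1 with 9 confirmation models
over 10 master seeds. Comparisons against printed reference values are
made at 4 decimal places (the precision of those tables) while all
internal arithmetic is double precision; sum-of-squares conservation is
asserted at $10^{-9}$ relative, where only floating-point error
remains.

## Known limitations

* Only the $L_9(3^4)$ design is provided; no interaction columns, no
  mixed-level arrays, and the screen estimates main effects only — a
  strong A×B interaction can in principle mislead it (the surrogate
  tests keep interactions an order of magnitude below the main
  effects, which is the assumption the method itself makes).
* Only the smaller-the-better SNR is implemented; larger-the-better and
  nominal-the-best variants are out of scope.
* The voting module is strictly binary with `ALL` as the positive
  class; weighted or probability-averaging ensembles are not included.
* The tiny CNN is a reference implementation for testing the contract,
  not a competitive image classifier.
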