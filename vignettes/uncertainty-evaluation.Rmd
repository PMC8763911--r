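---
title: "Quantifying and evaluating predictive uncertainty with uqeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and evaluating predictive uncertainty with uqeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uqeval)
```

## The problem

A classifier deployed in a high-stakes setting — say, screening chest
radiographs — is wrong on some fraction of its inputs. Point predictions
hide that: a softmax output of 0.51 and one of 0.99 both yield the same
label. The practical question is whether the model can *flag its own
likely errors*, so that flagged cases can be routed to a human for a
second opinion. `uqeval` implements the two halves of that question:

1. **Quantification** — turn a classifier into an approximate predictive
   posterior and a per-sample uncertainty score;
2. **Evaluation** — measure, objectively, how well that score separates
   erroneous from correct predictions, and how calibrated the underlying
   probabilities are.

## Posterior approximation

Exact Bayesian inference over network weights is intractable, so the
package implements three standard sampling approximations behind one
contract (`predict_proba()` / `n_classes()` / `supports_stochastic()`):

* **Monte Carlo dropout (MCD).** With dropout kept active at test time,
  each forward pass samples a thinned network; averaging `T` passes
  approximates the predictive mean,
  \(\mu_{pred} \approx \frac{1}{T}\sum_t p(y = c \mid x, \hat\omega_t)\).
  The default `passes = 200` gives a Monte Carlo standard error on each
  mean probability of at most \(0.5/\sqrt{200} \approx 0.035\), small
  relative to the effects the evaluation metrics measure.
* **Deep ensembles.** Independently trained networks (different
  initialisations and, here, different architectures) are each evaluated
  once, deterministically; the member mean is the predictive probability.
  The default ensemble size is 30.
* **Ensemble MC dropout (EMCD).** Every ensemble member is itself
  evaluated by MC dropout; the grand mean over `members × passes` draws
  is the posterior. With one member this reduces exactly to MCD, and
  with dropout-free members exactly to the ensemble — both identities
  are asserted draw-by-draw in the test suite.

Draws are stored as an `S × N × C` array rather than streamed: at the
problem sizes this package targets the array is at most a few hundred
megabytes, and keeping the draws makes the mean and variance
independently re-checkable.

One published formulation of the ensemble entropy omits the minus sign;
entropy is non-negative by definition, so the package computes
\(PE = -\sum_c \bar p_c \log_b \bar p_c\) everywhere, with the convention
\(0 \log 0 = 0\).

### Seed policy

Every source of randomness — data generation, weight initialisation,
mini-batch shuffling, dropout masks — derives from one master seed
through a fixed affine map on \((\mathrm{seed}, \mathrm{member},
\mathrm{pass})\). Consequences: posterior draws are bit-reproducible;
results do not depend on how a batch is partitioned; and member streams
are mutually independent. Inside the compiled kernel, dropout masks come
from a PCG32 generator seeded from R's RNG stream, which keeps
reproducibility under `set.seed()` while making mask generation cheap.

## The uncertainty score and its log base

Per-sample uncertainty defaults to the predictive entropy of the
posterior-mean probabilities. The log base defaults to **2**: for a
binary task this puts PE on \([0, 1]\), so a threshold grid spanning
0.1–0.9 covers the full range (natural-log binary entropy caps at
\(\ln 2 \approx 0.693\), which would make thresholds above 0.7 vacuous).
Natural log is available via `entropy_base = exp(1)`. The evaluation
metrics themselves are score-agnostic: any non-negative per-sample score
placed in the `uncertainty` column of a `labeled_predictions()` table is
accepted.

## The uncertainty confusion matrix

Crossing correctness (prediction vs ground truth) with certainty
(uncertainty vs threshold) yields four outcomes — TC, TU, FU, FC — and
four metrics: USen (errors flagged / all errors), USpe (correct kept /
all correct), UPre (errors flagged / all flagged), UAcc (diagonal / all).
Numerical conventions, all deliberate:

* *Strict comparison.* A prediction is uncertain iff its score strictly
  exceeds the threshold; ties count as certain. This makes "threshold at
  the maximum possible entropy flags nothing" exact.
* *Undefined, not zero.* A zero denominator (e.g. USen on an error-free
  batch) yields `NA`, which propagates to reports as an empty CSV cell or
  JSON `null` — never 0 or 1, which would silently flatter or slander a
  perfect batch.
* *Monotonicity.* Raising the threshold shrinks the flagged set, so USen
  is non-increasing and USpe non-decreasing in the threshold; this is a
  theorem (set inclusion) and is asserted on random instances. The
  empirical tendency of UAcc and UPre to rise with the threshold on
  high-accuracy models is *not* a theorem and is only observed on the
  synthetic study, not asserted universally.

The default sweep grid is 0.1–0.9 in steps of 0.1. 0.3 sits on the grid
and is the default single evaluation threshold — a reasonable trade-off
point between sensitivity and specificity on binary-entropy scales.

## Calibration

`bin_predictions()` uses `M = 10` equal-width bins on confidence (the
max of the posterior-mean probabilities), left-open right-closed with 0
in the first bin: a sample with confidence `p` lands in bin
\(\lceil pM \rceil\). Empty bins carry weight zero and report `NA`.
ECE is reported both as a fraction and ×100, since the field usually
prints it on the percent scale. The degenerate `M = 1` case collapses to
`|overall accuracy − mean confidence|`, which the tests use as an anchor.

## The synthetic task and what it does (not) show

The generator draws two isotropic Gaussian classes at mean separation
\(\Delta\) with spread \(\sigma\), equal priors by default (a 25/75
imbalanced preset, `"cxr-like"`, mirrors a screening cohort and is off by
default). Isotropic Gaussians were chosen because the Bayes error has the
closed form \(\Phi(-\Delta/(2\sigma))\) — an analytic anchor no private
image dataset can provide. The reference study condition is
\(\Delta/(2\sigma) = 1\) (Bayes error \(\approx 0.159\)): hard enough
that a well-trained classifier leaves a substantial population of
errors for the uncertainty machinery to find, which emulates an imperfect
medical-image classifier.

The fixture classifier is a dropout multilayer perceptron: two hidden
layers of 32/16 ReLU units, dropout 0.25, trained 200 epochs with Adam at
learning rate 0.001 (mini-batches of 256) on a 75/25 train/validation
split. Ensemble members draw their depth (2 or 3 hidden layers) and
widths (from per-layer ranges (16–64), (8–32), (4–16)) at random — the
deliberate architectural diversity that makes ensembles work. These are
desk-scale analogues of the wide fully connected heads used on top of
convolutional feature extractors in production models; widths are
configurable when more capacity is wanted.

What passing the synthetic study shows: on a task where errors are
genuinely ambiguous cases near the decision boundary, all three
posteriors put visibly more entropy on misclassified than correctly
classified samples (positive group gap in ≥ 27 of 30 seeds), reach test
error within 0.05 of the Bayes floor (median of 30 seeds, 2000 train /
2000 test points per seed — sizes chosen so the whole study runs in
minutes on one CPU), and admit a sweep threshold whose median USen ≥ 0.7
with median USpe ≥ 0.5. What it does *not* show: behaviour under
distribution shift, label noise, class imbalance at scale, or the
feature-learning failures of real image models — the Gaussian task has no
analogue of any of these, and the near-zero ECE of the fixture (a small
model on an easy feature space) should not be read as a claim that large
pretrained networks are calibrated; published evidence is that they are
typically overconfident.

There is no quantitative published effect size for the entropy gap
between correct and incorrect groups; the 27/30-seeds sign criterion and
the USen/USpe levels above are this package's own engineering choices
for a reproducible continuous-integration property, not claims imported
from elsewhere.

## Degenerate inputs and tie-breaks

* Argmax ties resolve to the lowest class index (documented because real
  posteriors essentially never tie exactly).
* Across-draw variance uses the unbiased (\(S-1\)) denominator and is
  defined as 0 for a single draw.
* Probability rows must sum to 1 within 1e-6 in memory; file readers
  accept 1e-4 and renormalise, absorbing text round-tripping.
* A single-class label vector is rejected at training; a prediction table
  with only correct (or only incorrect) rows yields a flagged one-group
  summary and `NA` gap.

## Interfaces

Prediction tables travel as CSV/JSON with a fixed schema (`sample_id`,
`true_label`, `prob_c0..prob_c{C-1}`, optional `uncertainty`); when the
uncertainty column is absent the reader fills it with predictive entropy
and records that provenance. Reports are deterministic in field order and
byte-identical under a fixed seed; CSV rounds to 4 significant digits,
JSON keeps full precision. The command-line tool (`inst/cli/uqeval.R`)
is a thin wrapper over the exported functions — `simulate`, `train`,
`posterior`, `evaluate`, `sweep`, `calibrate`, `study` — and produces
numbers identical to the library path for identical seeds.

## Known limitations

* The fixture trainer is plain Adam on full feature vectors; there is no
  convolutional front end, no early stopping, and no recalibration
  (temperature scaling is out of scope — evaluation only).
* The closed-form Bayes error requires equal priors and isotropic
  spread; for other configurations the generator still works but
  `bayes_error()` refuses rather than approximate.
* The uncertainty confusion metrics condition on a single threshold; they
  do not summarise the whole operating curve the way AUC does for
  classification. The sweep table is the intended raw material for such
  summaries.
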