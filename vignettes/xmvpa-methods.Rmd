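---
title: "Explainable fuzzy-rule MVPA for fNIRS: model, learning and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable fuzzy-rule MVPA for fNIRS: model, learning and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xmvpa)
```

## The model

`xmvpa` decodes a binary stimulus condition from a trials × channels
matrix of fNIRS features with a rule base of at most 20 linguistic
patterns. A pattern is a conjunction of up to three antecedents, each
pairing a channel with a conceptual label (CoL) of its activity —
*inactive*, *active* or *very active* — and a consequent stimulus class.
Keeping the rule set small and the antecedents short is what makes the
fitted model directly readable by a cognitive neuroscientist.

Each CoL is an **interval type-2 fuzzy set**: at any feature value `x`,
membership is an interval `[mu_lower(x), mu_upper(x)]` rather than a
single number. This interval encodes uncertainty in where, say, "active"
begins — which is substantial in infant data with high inter-subject
variability. Both bounds are piecewise-linear: *inactive* is a left
shoulder (flat 1 on the low side), *active* a trapezium, *very active* a
right shoulder. Counting breakpoints per bound, a channel's three CoLs
cost `(2+2) + (4+4) + (2+2) = 16` free parameters.

### Shape realisation

Only the parameter counts (4 / 8 / 4) and the qualitative shapes are fixed
by the method; this package realises the interval sets as **fully free
nested breakpoints**: the lower bound has its own breakpoints, constrained
so its graph sits under the upper bound's. The alternative — a lower
function sharing slopes with the upper — admits the same counts; free
breakpoints are the more general choice and the repair operator (below)
makes them safe.

Evaluation conventions: left of a left shoulder membership is 1 (and
symmetrically for right shoulders); outside any support it is 0;
zero-width edges (equal breakpoints) evaluate as step functions rather
than raising errors, because the evolutionary search will happily propose
them.

### Repair

The genetic algorithm proposes unordered reals. `repair_mf()` maps any
finite 16-vector to a valid channel concept set by (1) sorting each
bound's breakpoints and (2) clipping the lower function into the upper
one. The clip sequence is chosen so that the map is **idempotent** — a
repaired set passes through unchanged — which makes the genome-to-model
decoding a well-defined canonical form. The nesting guarantee
`mu_lower(x) <= mu_upper(x)` for all `x` follows from an endpoint argument
on each linear piece and is property-tested over 10,000 random draws in
the test suite.

## Features

The multivariate matrix entry `(i, j)` is the arithmetic mean of channel
`j` over a post-stimulus window in trial `i` — by default 4–7 s, where the
haemodynamic response peaks. The window is treated as a **closed
interval** with a tiny floating-point tolerance at the endpoints; the
printed convention "4−7 s" does not specify endpoint handling, and closed
is the reproducible choice. No baseline subtraction or z-scoring is
applied: the CoL numeric ranges are *learned per channel from the data*,
so they absorb scale and offset, and normalisation upstream is the
caller's business. `grid_search_window()` scores candidate windows by any
user-supplied objective (conventionally the mean cross-validated MCC, for
consistency with the training cost) and breaks ties by earliest start,
then shortest duration.

## Dominance scores and prediction

For pattern `q` with consequent class `Y_q`, activation strength on a
trial is the **product t-norm** over its antecedent membership bounds
(applied bound-wise). The product is standard in evolutionary-fuzzy rule
learning and, unlike the minimum, lets every antecedent modulate the
strength. On a training set of `N` trials:

- confidence per bound: `c_b = sum_{y_i = Y_q} w_b(x_i) / sum_i w_b(x_i)`
  (0 if the pattern never activates);
- support per bound: `s_b = sum_{y_i = Y_q} w_b(x_i) / N`;
- dominance score: `DS_b = c_b * s_b`.

One subtlety: because the confidence ratio has the same bound in numerator
and denominator, the two confidences need not come out ordered (the lower
bound can concentrate on the pattern's own class). The pair is therefore
reported as a sorted interval, after which `DS_lower <= DS_upper` holds
automatically. The single dominance score printed in rule reports is the
interval midpoint — the same averaging the association degree uses.

Prediction assigns the consequent of the pattern with the highest
association degree `h_q(x) = (w_upper * DS_upper + w_lower * DS_lower)/2`.
Ties break deterministically: larger dominance midpoint, then lower
pattern index. A trial with `h_q = 0` for every pattern is labelled
`"unclassified"`.

### The abstention penalty

`"unclassified"` is scored as the *wrong* class: it increments FN when the
truth is positive and FP when it is negative. The harsher alternative to
a majority-class fallback, it prevents abstention from inflating any
metric. A consequence worth knowing: an abstaining classifier has
expected MCC *below* zero under the null (with `u` abstentions and `a + b`
classifications, the expected MCC numerator is `-[u(a+b) + u^2]/4`), so
"MCC ≈ 0 for uninformative predictions" only holds for classifiers that
always answer. The permutation test is unaffected — observed and permuted
runs carry the same penalty.

## Evolutionary learning

One genome jointly encodes the rule base and all CoL ranges:

- per pattern (×20): 3 channel genes (0 = "don't care", enabling patterns
  shorter than 3 antecedents), 3 label genes, 1 consequent gene — 140
  integer genes;
- per channel (×10): 16 breakpoint genes — 160 reals;
- total: 300.

Decoding drops don't-care slots, deduplicates channels within a pattern
(first occurrence kept), drops empty patterns, and repairs the concept
block, so *every* finite genome is a valid model. The consequent is
evolved, not derived from confidence, as it is part of the encoding.

The cost of a genome is `1 − mean k-fold validation MCC` (k = 5): the
folds are stratified, fixed from the run's seed *before* the search
starts, and dominance scores are refitted on each training fold — no
information flows between folds or from validation labels into the
scores. A fold that ends up single-class (impossible under stratification,
possible with exotic user folds) scores MCC 0 with a warning.

Search operators: tournament selection (size 3), uniform per-gene
crossover (rate 0.9), mutation at rate `1/length` — random reset for
integer genes, Gaussian perturbation for breakpoint genes with s.d. 10 %
of the channel's data range. The best individual survives unchanged
(elitism 1), so the best cost is non-increasing. None of the operator
rates are prescribed by the method; these are conventional defaults and
all are exposed in `ga_config()`.

Two stopping rules: the stated tolerance `1e-5` on the **absolute cost**
(the flowchart compares the tolerance with `1 − mean MCC` itself, not with
its improvement), and a generation cap (default 500) because on noisy data
the tolerance alone may never trigger. The initial population seeds the
concept blocks from per-channel data quantiles (`default_bank()`) with
Gaussian jitter — the pattern genes are uniform random — which speeds up
convergence considerably without biasing which rules are found.

Runs are exactly reproducible from `rng_seed`; the RNG state of the
calling session is saved and restored around every seeded entry point.

## Permutation baseline

`permutation_test()` re-runs a user-supplied evaluation (typically the
full fit-and-score pipeline at a reduced budget) under randomly permuted
labels and reports add-one p-values `p = (1 + #{null >= obs}) / (1 +
n_perm)` — reversed for FPR/FNR, where smaller is better. The add-one
estimator is valid (conservative) at any permutation count, which matters
at desk scale where 99 permutations stand in for the reference 5,000.
Whether the original baseline refit the model per permutation or only
rescored a fixed model is not stated; refitting is the default here since
it is the only version whose null actually contains the selection
optimism of the search, and rescoring can be had by passing a fixed-model
evaluation function.

## The synthetic world

`generate_matrix()` emulates the reference study's dimensions — 19
subjects, 524 trials, 10 channels, two balanced classes — with planted,
recoverable structure. The three activity levels sit at centres 0, 1, 2
(arbitrary HbO2 change units); channels named by a planted rule of the
trial's class are drawn `Normal(centre, 0.3)`, so adjacent levels are
separated by more than 3 s.d.; unnamed channels draw their level uniformly
at random per trial (class-independent by construction); a per-subject
intercept `Normal(0, 0.1)` emulates inter-subject variability. The
defaults plant two rules — channels 1, 2, 4 *active* for the first class;
channel 1 *inactive* with channel 9 *active* for the second — mirroring
the occipital/temporal dissociation the method is meant to surface.

`generate_epochs()` wraps each planted amplitude in a gamma-shaped
haemodynamic bump peaking inside the analysis window, normalised so the
kernel's discrete window mean is exactly 1: at zero noise,
`window_mean_matrix()` returns the planted matrix bit-for-bit, which gives
the feature extractor an analytic oracle.

What the generator does *not* model: temporal autocorrelation, systemic
physiology (Mayer waves), motion artifacts, channel-wise noise
heterogeneity, or unbalanced designs. A green end-to-end recovery test
therefore establishes that the estimator works when its assumptions hold —
not that it is robust to real-world fNIRS nuisance structure.

## Numerical and degenerate-input choices

- Membership breakpoints must be finite; NaN/Inf raise errors at
  construction, not during evaluation.
- `0/0` metric ratios (e.g. NPV of an all-positive predictor) are reported
  as 0 with a warning; an MCC denominator with a zero factor gives MCC 0.
- Constant channels make quantile seeding impossible and raise an error
  naming the channel.
- JSON serialisation uses 17 significant digits, so concept banks and rule
  bases round-trip doubles exactly; equal seeds give byte-identical
  artifacts.
- Integer-gene values are rounded and clamped at decode, so any real
  vector is a legal genome.

## Known limitations

- Strictly binary classification; the confusion-matrix machinery assumes
  one positive and one negative role.
- The confidence/support/activation forms follow the standard fuzzy
  association-rule definitions; where the method leaves their exact
  functional form open, these are stated package decisions.
- Trial-level (not subject-level) fold stratification: with few subjects
  and strong subject effects, cross-validated MCC can be optimistic about
  generalisation to new subjects.
- The GA is single-objective; rule-set complexity is capped (20 × 3), not
  optimised.
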