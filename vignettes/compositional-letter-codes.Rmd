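---
title: "Compositional letter codes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional letter codes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lettercode)
```

## The modelling problem

How hard a jumbled word is to read tracks how visually similar it is to
the original word. `lettercode` implements a purely visual account of
that similarity, built in three steps:

1. **Perceptual distances from search times.** In oddball visual search,
   the time to find one string among copies of another indexes their
   similarity; the reciprocal of the mean correct search time, `d = 1/RT`
   (units 1/s), behaves like a perceptual distance (it is the rate of
   evidence accumulation, and it combines roughly linearly across
   factors).
2. **Artificial letter-tuned neurons.** Classical multidimensional
   scaling of the single-letter distance matrix places letters in an
   n-dimensional space whose Euclidean distances approximate `d`. Each
   dimension is read as one neuron's tuning curve over letters. Ten
   dimensions are the default; the variance-explained curve
   (`variance_explained_curve()`) shows what any other choice buys.
3. **Compositional string responses.** A neuron's response to a string
   is a weighted sum of its single-letter responses,
   `r_k(s) = sum_p w[k, p] * r_k(s[p])`. There are no string-specific
   detectors: positions enter only through the per-neuron spatial
   summation weights `w`. Dissimilarity between equal-length strings is
   the distance between their response vectors.

Transposed strings (AB vs BA) get identical responses whenever the
weights are position-symmetric; discriminating them *requires*
asymmetric summation in at least one neuron. The modulation index
`|w1 - w2| / |w1 + w2|` summarizes that asymmetry per neuron on [0, 1].

Downstream, the same geometry models word recognition: a nonword in a
lexical decision task is rejected more slowly the closer it lies to its
nearest stored word (`RT = 1/(alpha d + beta)` on the reciprocal scale),
while word responses are dominated by log word frequency. An edit
distance with substitution cost 2 (`old_distance()`) and a
lexical-factor regression serve as baselines, compared by
cross-validated bootstrap splits over subjects. Finally, the RSA module
relates model distances to multi-run activation patterns through
cross-validated (leave-one-run-out) Mahalanobis distances, which are
unbiased and may legitimately be negative under the null.

## Fitting the summation weights

`fit_weights()` minimizes the squared error between observed and
predicted dissimilarities over the `neurons x positions` weight matrix
(20 free parameters for bigrams with a 10-neuron code). The objective is
smooth for the Euclidean metric away from coincident responses, and we
supply the analytic gradient to BFGS (`reltol = 1e-14`, up to 1000
iterations). Because the predicted distances are invariant to flipping
the sign of any single neuron's weight row, recovered weights are
identified only up to per-neuron sign; comparisons with ground truth
must take the better of the two signs per neuron. The fit is also
1-homogeneous: scaling all weights by c scales every distance by c, so
the data's overall scale is absorbed by the weights and the letter code
is deliberately not re-normalized before fitting.

The model is nonlinear in `w`, so the optimizer restarts from
`n_restarts` (default 10) standard-normal initializations and keeps the
lowest final loss. On noiseless synthetic data the global optimum is
recovered to machine precision; the restart count matters mainly for
noisy, nearly-symmetric regimes.

Two distance metrics are provided. `euclidean` (default) is the
Euclidean distance between response vectors and is a true pseudometric;
`mean_abs` averages per-neuron absolute response differences. Both are
fit by the same machinery; the choice is surfaced because the two
conventions coexist in the field.

**A caution about shuffle controls.** A common check is to refit after
randomly shuffling the observed dissimilarities and verify that some
structure (here, positional asymmetry) disappears. For this model the
check behaves counterintuitively: after shuffling, transposed pairs
receive typical-magnitude target dissimilarities, and positional
asymmetry is the only mechanism that can give transposed pairs any
predicted distance at all — so a fully converged least-squares fit to
shuffled data is *more* asymmetric than the fit to intact data, not
less. We verified this is the global optimum (identical loss and
asymmetry across dozens of restarts, under both metrics). The package
therefore reports the shuffled-to-intact asymmetry ratio as a
diagnostic, and the test suite documents the converged behavior; a
drop in asymmetry under shuffling should not be expected from this
estimator.

## The part-sum alternative

`build_design()` + `fit_part_sum()` express string dissimilarity as a
linear combination of single-letter dissimilarities across location
pairs, `D(s, t) = sum_{i,j} c[i,j] d(s[i], t[j])`, estimable uniquely by
ordinary least squares when the design has full column rank (an
intercept is included by default; both choices are explicit arguments).
`reduce_model()` ties coefficients into classes — by default by location
separation `|i - j|`, which for bigrams collapses four coefficients to
two — and refits; being nested, the reduced in-sample fit can never
exceed the full one, which the tests exploit as an invariant. The tying
rule is a plain function argument so alternative reductions need no
code changes.

The part-sum and letter models coincide exactly on string pairs that
differ at a single location. Over all pairs they differ: the letter
model takes the absolute value of a *signed* sum of per-position
response differences, while the part-sum predictors are unsigned
dissimilarities, so agreement degrades when per-position differences
have mixed signs (empirically r ~ 0.87 for a one-neuron code on all
bigram pairs, r = 1 on single-location pairs).

## Preprocessing choices

* **Outlier removal** (`filter_outliers()`): within each search pair,
  trials beyond `k = 3` scaled median absolute deviations from the
  median are dropped; the scaling constant is fixed at 1.4826 (Gaussian
  consistency, matching the common `isoutlier` convention). Groups of
  one trial are kept. The rule is applied once; because removing points
  shrinks the MAD, a second application can remove more — the filter is
  a fixed single-pass rule, not a fixed point, and tests treat it as
  such.
* **Dissimilarity** (`dissimilarity_from_trials()`): reciprocal of the
  mean RT over all retained correct trials of a pair, both target
  assignments pooled. The mean-of-reciprocals alternative is one
  argument away for sensitivity analysis. Incorrect trials are dropped
  before everything else.
* **Reliability** (`split_half_consistency()`): Pearson correlation (by
  default) between per-half pair statistics over `n_splits = 100` random
  subject partitions, plus the deterministic odd/even split, corrected
  to a full-data bound by `spearman_brown()` (`2r/(1+r)`). Spearman
  correlation is available by argument since conventions differ.

## Lexical-decision modelling choices

* **Neighborhood**: substitution-only same-length neighbors (Coltheart's
  N) by default; an edit-distance-radius alternative is selectable.
* **Nearest word**: restricted to same-length words because the
  compositional model requires aligned positions; `old_distance()`
  covers cross-length comparisons. Ties go to the lexicographically
  first word, for determinism.
* **Frequency floors**: zero or unseen frequencies are floored at half
  the smallest positive norm frequency before taking logs.
* **Targets**: word models regress RT, nonword models reciprocal RT
  (the distance model is linear on that scale); both are arguments.
* **Model comparison** (`crossval_compare()`): subjects are halved at
  random `n_boot = 1000` times; models are fitted to train-half
  per-string means and scored on test-half means. The exceedance
  probability counts exact ties as 1/2, so literally equivalent models
  calibrate to p = 0.5 rather than 0; for distinct models ties have
  probability zero and the convention is inert.
* **Accuracy exclusions**: low-accuracy nonwords can be excluded before
  modelling (threshold an argument, conventionally 20%); the synthetic
  generator holds accuracy at ceiling, so this path matters only for
  real data.

## RSA choices

`crossnobis()` computes, for each condition pair and leave-one-run-out
fold, the inner product between the held-out pattern difference and the
mean difference over remaining runs, averaged over folds. With no noise
it equals the squared Euclidean distance between condition means; under
the null its expectation is zero (the two factors carry independent
noise), which is what distinguishes it from a plain distance and why
negative values are kept. Whitening defaults to the identity; a noise
covariance can be supplied and is inverted once (an error names the rank
if it is not positive definite). Subject aggregation applies the same
MAD rule as the RT module per pair, then takes the median.
`rsa_correlation()` bootstraps over pairs (1000 resamples) with a
one-sided p for positive correlation, matching how directional claims
are made in this literature. `partial_correlation()` uses the standard
closed form and refuses degenerate conditioning (`|r| = 1` with the
covariate): the formula is 0/0 there and a silent 0 would hide an
input error.

## What the synthetic generator does and does not emulate

The generator produces every input the pipeline consumes:

* **Search trials**: each unordered pair appears `n_reps` times per
  subject with either member the target equally often; the RT law is
  exactly reciprocal, `1/RT = d/rt_scale + baseline` (baseline 0 by
  default), with multiplicative lognormal trial noise (`noise_sigma`,
  dimensionless log-sd). Lognormal noise was chosen because RTs are
  positive and right-skewed; the family is an argument of convenience
  in the sense that `noise_sigma = 0` recovers the deterministic law
  the tests rely on. Accuracy is held at ceiling.
* **Lexica**: unique random words with Zipf frequencies
  (`rank^-exponent`, exponent 1 by default). The nonword scheme mirrors
  the standard manipulation taxonomy (edge/middle adjacent and two-step
  transpositions, random reshuffles, edge/middle substitutions by
  letters absent from the word, combined substitution-permutation);
  two-step transpositions require length >= 5 and the generator refuses
  schemes that demand them of four-letter words. Words that cannot
  realize a category (e.g. a swap across identical letters) are skipped
  in favor of another pool word.
* **Lexical decisions**: word RT `a - b log f`, nonword RT
  `c/(alpha d_nearest + beta)`, additive Gaussian noise, truncated
  positive. Defaults (a = 0.65 s, b = 0.03 s, c = 0.8, alpha = 1,
  beta = 0.6, noise 0.04 s, 16 subjects) give RTs in the 0.4-0.9 s
  range typical of speeded word/nonword classification.
* **Voxel patterns**: condition means plus i.i.d. Gaussian noise per
  run; **embeddings**: exactly orthonormal cluster centers plus jitter,
  so cosine anchors (0 within, 1 across) are exact at zero noise.

Real data differ in ways the generator deliberately ignores: RT noise is
correlated within subjects, accuracy is below ceiling, letter confusions
are not isotropic, lexica have morphology and phonology, and fMRI noise
is spatially and temporally structured. Passing tests therefore certify
the *estimators* (they recover known structure and are calibrated under
their own assumptions), not the empirical claims one would make from
behavioral or imaging data.

One realism choice deserves emphasis: the end-to-end lexical-decision
study uses a *sparse* lexicon (40 five-letter words over a 20-letter
alphabet). With dense random lexica, substitution nonwords end up closer
to some unrelated word than to their source, saturating
distance-to-nearest-word at the lexicon's packing radius and washing out
the edge/middle substitution contrast. Natural lexica occupy a
vanishing fraction of string space, so sparsity is the realistic regime,
and under it the classic ordering (transpositions harder than
substitutions, middle manipulations harder than edge ones) follows from
an edge-weighted summation profile alone.

## Numerical conventions and degenerate inputs

* Classical MDS (`stats::cmdscale`) is deterministic; optional metric-
  stress refinement starts from the classical solution. Negative
  eigenvalues (1/RT matrices need not be Euclidean) are clipped to zero
  and their mass reported in `diagnostics`. Variance explained is
  reported both as cumulative eigenvalue share and as distance
  correlation; they answer different questions and are not collapsed.
* Pairs are stored unordered in canonical (sorted) order everywhere;
  duplicate pair rows are an error at construction.
* `rank_jumbles()` breaks distance ties lexicographically.
* Zero model dissimilarity in the search generator is an error naming
  the pair (the implied RT is infinite).
* The modulation index is undefined when `w1 + w2 = 0` and errors for
  that neuron rather than returning Inf.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data
at the sizes the analyses were designed around: 62 single characters
(1891 pairs), 49 bigrams (1176 pairs), a 450-word/450-nonword lexical
set for the scheme arithmetic, a 40-word sparse study with 16 subjects
for end-to-end checks, 1000 null simulations for crossnobis calibration
and 1000 subject splits for model-comparison calibration. The complete
pipeline demo (`run_pipeline()` with defaults) covers a 10-letter
alphabet, 5 neurons, 100 words and 6 subjects and finishes in seconds.

## Known limitations

* The letter model requires equal-length strings; cross-length
  comparisons fall back to the edit-distance baseline.
* Per-neuron sign ambiguity means raw weight values are not
  interpretable in isolation; compare distances or sign-aligned weights.
* The part-sum reduction tied by `|i - j|` is one of several defensible
  reductions; the class rule is an argument precisely because the
  five-parameter variant used for six-letter strings in the literature
  does not follow from separation tying alone (six classes, not five).
* The shuffle control caveat above: destroyed data does not reduce
  fitted positional asymmetry under converged least squares.
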