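---
title: "Behavioral age from smartphone touchscreen dynamics: methods"
author: "tapage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral age from smartphone touchscreen dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`tapage` implements a normative-modelling pipeline for smartphone
*tappigraphy* -- the time series of touchscreen interaction timestamps. The
idea mirrors brain-age modelling: train a regression in a healthy population
to predict chronological age from behavior, then deploy it on a patient
cohort and read the systematic prediction error ("behavioral age gap",
predicted minus real age, positive meaning older-looking behavior) as an
index of accelerated aging.

The pipeline is: tap streams → inter-touch intervals (ITIs) → joint
interval distribution (JID) features → gradient-boosted age regression
under 10-fold cross-validation → Shapley attribution → bootstrap
age-matched deviation analysis.

# The joint interval distribution

For one subject, ITIs are the differences between successive interaction
timestamps (milliseconds). Each ITI at position *k* is paired with its
successor at *k + 1*, and the pairs are mapped to
$(\log_{10} \mathrm{ITI}_k,\ \log_{10} \mathrm{ITI}_{k+1})$. A 2D Gaussian
kernel density estimate (isotropic, bandwidth 0.1 in log10 units, no cross
term) is evaluated at 50 × 50 equally spaced cell centers spanning
log10-ms 0.5 to 5 (about 3 ms to 28 h), and the cell values are
renormalised to a probability mass summing to one. Rows index the interval
at *k*, columns the interval at *k + 1*; fast--fast typing bursts live in
the lower-left corner, pauses in the upper right, and transitions off the
diagonal.

Numerical choices worth stating explicitly:

* **Centers vs edges.** Density is evaluated *at the 50 centers* and
  converted to mass by renormalisation. Probability-mass normalisation
  makes the bin features and the entropy scale-free; kernel mass falling
  outside the grid is implicitly discarded by the renormalisation, and
  pairs outside the span still contribute to in-grid cells (no
  pre-clipping).
* **Zero intervals.** Duplicate timestamps would give $\log_{10} 0$;
  they are dropped before pairing.
* **Day boundaries.** Pairs are never formed across midnight: an
  overnight gap is not a behavioral interval, and letting it in would pile
  artifactual mass onto the slow tail. A run of *m* same-day events yields
  *m − 2* pairs. This rule is a documented package choice; with the grid
  ceiling at $10^5$ ms such gaps would in any case be marginal.
* **Entropy.** Shannon entropy $-\sum p \log_2 p$ of the 2500 cells, in
  bits, with $0 \log 0 := 0$; bounded by 0 and $\log_2 2500 \approx
  11.288$. The base is a package choice (tree models are insensitive to a
  constant rescaling of one feature).

The implementation (`computeJID`) is a vectorised separable kernel sum; the
test suite holds it to within $10^{-10}$, elementwise, of a literal
double-loop over pairs × cells.

# Feature vector

Per subject, 2504 ordered features: the 2500 JID cells (row-major, interval
at *k* major), then `gender_code` (0 male, 1 female), `jid_entropy` (bits),
`log10_median_daily_taps` (log10 of the median per-day interaction count
over days with data), and `screen_size` (inches). Chronological age is the
regression target and is kept out of the feature block. Missing covariates
are an error; nothing is imputed.

# Normative model

Gradient-boosted regression trees (xgboost), squared-error objective, with
the fixed configuration: maximum depth 9, 567 trees, learning rate 0.01,
minimum child weight 8, L1 alpha 0.001, column and row subsampling 1.0.
These are frozen defaults of `modelHyperparams()`; hyperparameter search is
deliberately out of scope. Training is single-threaded and seeded so a
refit reproduces the bundle bit-for-bit.

Two algorithmic settings are package choices, not model hyperparameters:
histogram-based split finding (`tree_method = "hist"`) with `max_bin = 32`.
With 2504 features, exact greedy split enumeration makes a 10-fold bundle
impractically slow on one core; the histogram approximation changes
out-of-fold performance negligibly on the synthetic cohorts (we compared
32 against 64 and against exact split finding before freezing it).

Folds are age-stratified: subjects are sorted by age and dealt block-wise,
each consecutive block of *k* receiving a random permutation of the fold
labels, so fold sizes differ by at most one and fold age distributions are
matched. Out-of-fold predictions come only from the model that never saw
the subject. Performance is summarised by ME (mean signed error,
predicted − real), MAE, and R². **R² here is the squared Pearson
correlation** between predicted and real age -- the convention of the
normative-age literature this package sits in -- which is 1 for *any*
perfectly linear relation, including an anti-correlated one; the
coefficient of determination is also returned (`R2_cod`) for readers who
want the stricter quantity. Constant predictions make the correlation
undefined; it is reported as missing with a warning.

A "null input" (all-zero JID, zero covariates) produces a single
deterministic baseline prediction, useful as a reference point when
interpreting patient outputs.

# Shapley attribution

Attributions are exact, path-dependent tree-Shapley values computed by a
polynomial-time algorithm over the fitted trees, using the cover-weighted
conditional expectations the trees were trained with. The implementation
is in compiled code and works in double precision: the defining additivity
identity -- base value plus the sum of the 2504 attributions equals the
prediction -- holds to ~1e-12 per subject, and the package contract is
1e-6. (The xgboost library's own `predcontrib` computes the same
quantities in single precision, which accumulates ~1e-4 error at 567
trees; the test suite uses it as an independent cross-check at 1e-3
rather than as the implementation.) Predictions reported alongside
attributions are recomputed in double precision by routing each subject
down the parsed trees, mirroring xgboost's single-precision split
comparisons so the routing is identical.

One caveat we verified empirically and document rather than hide:
path-dependent tree-Shapley treats repeated splits on the same feature
along one root-leaf path jointly. For trees in which no path repeats a
feature it equals the exhaustive-coalition Shapley value of the
cover-expectation game exactly (the test suite checks random such trees
against a brute-force enumeration over all feature subsets); when a path
does repeat a feature the two can differ. This is a property of the
standard algorithm itself, shared by every mainstream implementation, not
an approximation introduced here.

Healthy subjects are attributed out-of-fold (by the one model that never
saw them); external cohorts are attributed by all fold models and
averaged. Population maps separate, per JID cell, the mean positive and
mean negative attribution, computed per subject *before* averaging so
opposing contributions do not cancel; their sum is the plain mean map.
Covariates are summarised separately.

# Deviation analysis

Patients are scored by all 10 fold models (their features must be built at
the bundle's accumulation window; a mismatch is an error). Per model, the
median signed error over patients gives 10 "typical errors". The null is
built by bootstrap: in each of 10,000 iterations, every patient is matched
to one healthy subject drawn uniformly from those within ±2 years of the
patient's age, without replacement within the iteration, and the median of
the matched subjects' *out-of-fold* errors is recorded (out-of-fold so the
null is not optimistically biased). Patients are matched scarcest-pool
first, and a thin pool raises an error rather than silently relaxing the
match. The two distributions are compared with a two-sample t-test --
Welch's unequal-variance form by default, the pooled form available as an
option since "two-sample t-test" underdetermines the variance assumption.
The headline number is the gap: mean(patient medians) − mean(null
medians), in years.

Per patient, predicted age (median over the 10 models; the mean is an
option) is regressed on real age by Huber M-estimation (IRLS, tuning
constant 1.345, the textbook default), with the slope t-statistic on
n − 2 degrees of freedom.

# The synthetic cohort generator

No public tappigraphy dataset ships with the package, so the generator
produces streams with the statistical structure the analysis assumes, and
everything downstream is tested against it.

ITIs are drawn from a four-component mixture of lognormals -- regimes at
log10-ms 2.0 (fast, ~100 ms), 3.0 (~1 s), 3.6 (~4 s) and 4.5 (~30 s) --
with first-order Markov persistence (default 0.65): the next interval
stays in the current regime with that probability, otherwise redraws from
the stationary weights. The persistence is what gives the JID its
off-diagonal structure; without serial dependence the JID would be an
outer product and carry nothing beyond the marginal. Age enters linearly
in the mixture-weight logits (softmax), with default slopes −0.030, 0,
+0.012, +0.024 per year: fast-interval mass falls and slow mass rises
with age, the direction reported for human smartphone use. The magnitudes
are invented -- there is no published generative law for ITIs -- and were
chosen once so the JID shifts visibly across the 16--86 year span; a
per-subject random logit offset (sd 0.25) adds stable individual
differences so same-age subjects do not share an identical law. Days are
simulated independently; sessions per day are Poisson (default mean 20)
with Poisson session lengths (mean 10 extra taps), session start pauses
lognormal around ~8 min, and events clipped at midnight. "Patients" are
generated at effective age = chronological + `accelerationYears` while
their metadata keeps the chronological age, so the deviation analysis has
a known ground truth to recover.

The master seed is split into per-subject substreams, so subject *i* is
reproducible regardless of cohort size.

What the generator does *not* emulate -- and hence what passing tests do
not show about real data: circadian and weekly rhythms, app-specific
behavior, notification-driven usage bursts, device changes, non-stationary
aging within a recording, and any realistic between-subject correlation
structure beyond the single logit offset. Results on this generator
validate the *machinery* (featurization, model plumbing, attribution,
bootstrap logic), not the human-level effect sizes.

# Problem sizes and runtime

The package's own validation runs use: a 300-subject healthy cohort
(ages uniform on 16--86, recordings 10--30 days, featurized at a 30-day
window) for parameter recovery, attribution additivity, null calibration
(20 replicates of 15 fresh null patients), effect recovery (20 patients
at accelerations 0/4/8/12 years) and duration sensitivity (5-day
truncation vs the full window); and a 120 + 20 demo cohort for the
end-to-end run. These sizes were chosen so the full suite completes in
tens of minutes on a single core while leaving the statistical checks
well-powered; on pilot runs the 300-subject cohort yields out-of-fold
R² ≈ 0.89 and recovers an injected 8-year acceleration to within a year.

# Known limitations

* **The bootstrap comparison is anti-conservative under between-subject
  heterogeneity.** The two-sample t-test compares 10 per-model patient
  medians — all computed on the *same* sampled patients, so their spread
  reflects only model-to-model disagreement — against thousands of
  bootstrap null medians, whose mean is estimated almost exactly. The
  sampling variance of the patient cohort itself (a fresh cohort's median
  error fluctuates by about ±1.6 years at n = 15 under the generator's
  default heterogeneity) enters neither variance term, so the test
  rejects far more often than its nominal level when the true
  acceleration is zero: in our 20-replicate null simulations roughly half
  the replicates reached p < 0.01. Interpret the gap in years, and its
  behavior across conditions, rather than the p-value; a well-calibrated
  alternative would need to resample patients, not just controls.
* The generator's effect sizes are arbitrary; headline numbers from human
  cohorts (MAE in years, specific t statistics) are not reproducible from
  synthetic data and are not claimed.
* The squared-correlation R² convention overstates fit quality whenever
  the prediction is linearly related but miscalibrated; compare `R2_cod`.
* The age-matching tolerance (±2 years) and without-replacement policy
  are package choices where the method description underdetermines them.
* Exact replication of any original JID matrices is not claimed: kernel
  normalisation at the grid edge and the centers-vs-edges choice admit
  several equivalent-after-renormalisation readings.
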