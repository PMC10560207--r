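---
title: "Verification from heartbeat-interval windows: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verification from heartbeat-interval windows: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own science: what is being
modelled, which knobs matter, which choices were genuinely open and how
they were settled, and what the synthetic experiments do and do not show
about real recordings.

## The verification problem

Given two windows of `n_beats` consecutive RR intervals, decide whether
they come from the same individual. The decision is binary and
threshold-based: a shared encoder maps each window into a latent space,
the cosine of the angle between the two embeddings is the similarity
score in [-1, 1], and a pair is accepted as genuine when the score
reaches the acceptance threshold (a score exactly at the threshold is
accepted; some tie-break had to be fixed and this one keeps the
acceptance region closed). Sweeping the threshold over the observed
scores traces the false acceptance rate (impostor pairs accepted) and
false rejection rate (genuine pairs rejected); their crossing defines the
equal error rate (EER). We follow the standard biometric semantics — FAR
counts errors on impostor pairs, FRR on genuine pairs.

## The synthetic cohort generator

Real longitudinal mouse RR recordings of this kind are access-restricted,
so the package generates cohorts whose structure matches that study
design: 30 subjects by default, recorded from 6 to 24 months of age at
3-month intervals, 10 min per visit under basal conditions and 40 min
after combined atropine/propranolol ("drug"), with occasional
out-of-range artifacts.

Each subject draws a persistent **signature** from population
distributions:

* `mean_rr` — baseline interval, centred at 0.132 s so that a 250-beat
  window spans ≈ 33 s, the scale typical of anesthetized mice
  (between-subject SD 0.012 s by default);
* `sd_rr` — within-subject variability (centre 0.010 s);
* `ar_coeffs` — two AR(2) coefficients drawn inside the stationarity
  triangle, giving subjects distinguishable short-range dynamics; draws
  outside the triangle are rejected and redrawn (bounded retries);
* `osc_amp`, `osc_freq` — one respiratory-like sinusoid in cycles/beat;
* `drug_var_scale` (default centre 0.4) and `drug_mean_shift` — dual
  autonomic blockade suppresses heart-rate variability, so the drug
  condition shrinks the generating SD and slightly shifts the mean;
* `aging_mean_drift`, `aging_var_drift` — linear drift per month past
  the 6-month reference, linear because it keeps age effects testable in
  closed form.

A segment is AR(2) noise around the (age/drug-adjusted) mean plus the
sinusoid, generated until the cumulative interval sum reaches the
requested duration; artifacts replace beats at the configured rate with
uniform draws from [0.26, 0.40] s or [0.01, 0.045] s, so every artifact
deterministically violates the 0.05–0.24 s physiological filter.

Two calibrated presets bound the difficulty axis. `high_separability`
widens between-subject spreads and shrinks within-subject noise — a
working verifier must reach a low EER on it. `degenerate` collapses all
population distributions to a point so that subjects are statistically
identical and any verifier must sit at EER ≈ 0.5. One subtlety was found
while validating that chance-level property: the sinusoid's phase is
drawn once per segment, so it persists across all windows of a subject
and is itself a usable biometric signature even when every named
signature field is identical. The degenerate preset therefore sets the
oscillation amplitude to zero; a preset whose defining property is
"no subject information" must not smuggle any in through phase. The
other presets keep the oscillation, where it is a legitimate part of the
signature.

No published within- versus between-subject HRV statistics exist for the
real cohort, so the presets cannot be calibrated to it; they are exposed
as configuration and the defaults are the package's own choice of a
realistic regime. The generator does not emulate circadian rhythm,
activity states, anesthesia depth, or R-peak detection noise — passing
tests on synthetic cohorts demonstrate that the pipeline and model work
as specified, not that any particular EER will be attained on real data.

## Preprocessing rules and their edge cases

RR intervals are the successive differences of R-peak times. The range
filter treats any interval outside [0.05, 0.24] s (bounds inclusive) as
an artifact and replaces it by linear interpolation **in beat index**
between the nearest in-range neighbours; interpolation in wall-clock time
would itself depend on the corrupted values, so the index domain is the
deterministic choice. Artifact runs at a boundary, having an in-range
neighbour on one side only, are filled flat with that neighbour. The
filter preserves length, touches only out-of-range positions, and is
idempotent. A series with fewer than two in-range intervals is rejected
as unusable.

Drug segments lose their first 120 s (measured in cumulative RR time
from the segment start, since the generator has no wall-clock
annotations) to avoid the injection transient. Windowing then takes
consecutive non-overlapping blocks of `n_beats` intervals and discards
the remainder. RR values enter the model in raw seconds — no resampling,
detrending or normalization — so the first batch-normalization layer is
the only input scaling.

## Pairing and protocols

The subject with the fewest basal windows defines the common count N and
every subject keeps its first N windows per condition, preventing long
recordings from dominating. Genuine pairs are all distinct same-subject
window combinations (optionally capped per subject for large pools); a
subject reduced to a single window contributes that window paired with
itself. Impostor pairs are sampled uniformly over cross-subject
combinations — without replacement until exhausted, then with
replacement — to match the genuine count. Under the `same` condition
policy both members of every pair share the recording condition, which is
how drug experiments are paired.

The CD split is per-subject over windows at 80/20 with the test share
rounded **up**, so every subject retains at least one test window (this
is what forces the single-window fallback above). The PD split is over
subjects, disjoint by construction, with an optional subject-disjoint
validation slice (default 20% of training subjects) for hyperparameter
tuning. Minibatches are exactly half genuine, half impostor; an epoch is
one shuffled pass over the genuine pairs, with the minority class
resampled with replacement.

## The model and its training

The encoder is three convolution blocks (1-D convolution with
"same"-style padding, batch normalization, max-pool of width 2, ReLU)
followed by two dense blocks (linear, batch normalization, ReLU,
dropout) and a final purely linear layer that emits the embedding. The
kernel size is `max(1, floor(n_beats / 10))` in all three convolutions
(rounding down; some rounding had to be picked). The channel and layer
widths are not dictated by anything external; the defaults
16–32–64 channels, dense 128–64–32, embedding 32, dropout 0.2 are
deliberate mid-size choices exposed in `siamese_config()`. Padding is
"same"-style so that only pooling changes the length, which makes the
flattened dimension `conv_channels[3] * floor(n_beats / 8)` predictable;
`n_beats >= 8` is required so three poolings leave at least one position.

Training minimizes

L(Θ) = (1/B) Σ (1 − y) c − λ y (b + c)

by SGD with momentum and weight decay (those two are the optimizer
hyperparameters worth tuning here; weight decay is not applied to batch
normalization parameters or biases, the usual convention). Defaults:
batch 32, learning rate 0.02, momentum 0.9, weight decay 1e-4, λ = 1,
b = 0. Both pair members pass through one stacked forward call so batch
normalization sees both branches; the branches share parameters by
construction, not by synchronization. Training aborts with a diagnostic
if the loss becomes non-finite. A seeded random search
(`tune_random_search`) over the stated ranges replaces any more
elaborate hyperparameter optimization.

One property of the loss deserves honesty: the offset `b` enters only
through the term −λ y b, which is constant in Θ. Its gradient is
therefore zero and two trainings differing only in `b` (same seed)
produce bitwise-identical parameters — `b` relabels the loss value
without changing the optimum. The test suite asserts exactly this,
together with the additive identity L(b₁) − L(b₂) = −λ(b₁ − b₂)/2 on
balanced batches. The tradeoff between the two error rates that `b` is
nominally meant to steer is in practice governed by λ (which genuinely
reweights genuine-pair gradients, and whose direction the tests check)
and by the decision threshold at evaluation time. `b` is kept in the
interface because it is part of the loss definition.

## Evaluation choices

The threshold grid is the set of unique observed scores plus sentinels
±1; between grid points FAR and FRR are step functions, and the EER is
taken at the first sign change of FAR − FRR by linear interpolation
between the bracketing thresholds (tolerance against an exhaustive scan:
1e-9 in the tests). Fold-wise statistics use disjoint random folds of
the scored pairs; a fold that lands single-class is redrawn a bounded
number of times before erroring. The confusion matrix has ground truth
in rows and predictions in columns. CV is σ/μ of the fold EERs and is
undefined (NA) when the mean EER is zero.

The TOST age-equivalence procedure runs two one-sided unpaired Welch
t-tests of the fold-EER difference against ±margin, with the margin
defaulting to three standard deviations of the reference-age fold EERs.
Equivalence is declared when the **sum** of the two p-values is below α —
that is the procedure this package mirrors — while the conventional
`max(p₁, p₂) < α` rule is available via `rule = "max"`. The sum rule is
more conservative than the max rule (the sum dominates the max), so a
verdict of equivalence under it also holds conventionally.

## Problem sizes

The test-suite and acceptance runs use cohorts the package chose to keep
the full train-and-verify cycle comfortable on a single CPU: the
separability checks train on thirty 6-month subjects with 600 s basal
segments, 50-beat windows, at most 40 genuine pairs per subject and
8 epochs — about 1,200 genuine training pairs, which is enough for the
high-separability preset to reach EER ≤ 0.25 and for the degenerate
preset to stay statistically at 0.5 (95% binomial band around one half).
Unit tests use smaller cohorts still. Larger cohorts, longer windows and
more epochs only extend these runs linearly; the window-length grid
25–600 in steps of 25 is the default sweep in `experiment_spec()`.

## Known limitations

* The generator's separability presets are self-calibrated, not fitted
  to any real cohort; absolute EERs on synthetic cohorts do not transfer
  to real animals or humans.
* AR(2)-plus-sinusoid dynamics are the minimal structure giving subjects
  distinguishable second-order statistics; real HRV has circadian,
  activity and nonlinear structure the generator does not attempt.
* The evaluation assumes scored pairs are exchangeable within a class;
  pairs sharing a window are not independent, so fold-wise SDs modestly
  understate the true sampling variability of the EER.
* Embeddings of constant windows can in principle collapse to zero norm,
  which the cosine rejects explicitly as a degenerate-embedding error
  rather than returning a silent 0.
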