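---
title: "Self-correcting recurrent networks for AKI early warning: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-correcting recurrent networks for AKI early warning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akiwarn)
```

## The prediction problem

For every hour `t` of an ICU stay the task is to predict whether the
patient will meet the urine-output criterion for acute kidney injury
(AKI) over the next 6 hours.  Following the RIFLE urine-output rule, a
patient is AKI-positive when the urine rate stays strictly below
0.5 mL/kg/h for 6 consecutive hours.  The label attached to hour `t`,

\[ y_t = \mathbf{1}\{\,u_s / w < 0.5 \ \text{for all } s \in (t, t+6]\,\}, \]

is therefore only observable at hour `t + 6`.  That delay is the crux of
the method: at hour `t` the true label for hour `t - 6` has just become
available, so a model that runs forward in time can legitimately consume
its own 6-hour-old prediction together with the matching ground truth —
at inference time as well as during training.  `next6_label()` implements
the strict reading in which the whole 6-hour window must fall inside the
horizon; this is the unique reading under which the label for `t` is
exactly observable at `t + 6`.  A lenient alternative
(`strict_window = FALSE`), which fires when any 6-hour window *ending* in
the horizon is low (so windows may straddle `t`), is provided for
sensitivity analyses but is not the default.  Ties at exactly
0.5 mL/kg/h do not count as low ("less than" is strict), and labels are
always computed from raw, imputed urine volumes — min-max normalization
would destroy the physical threshold.

## The model family

All models are stacked GRU (or LSTM) networks over hourly feature
vectors `x_t` with a sigmoid (classification) or linear (regression)
head on the top hidden state.

**Self-correcting feedback.**  At step `t` the pair
`(stop_grad(y_hat[t-6]), y[t-6])` — the model's own lagged prediction and
the now-observed truth — is passed through a small feedforward "feedback
network" (2 tanh layers of width `hidden_size / 4` by default) and the
resulting vector is concatenated onto the *input of every recurrent
layer*.  Discrepancies between the two entries tell the network how wrong
its hidden state was 6 hours ago, letting it correct the state online.
For `t <= 6` no label is observable yet, so trained default constants are
substituted; they are genuine parameters updated by backpropagation
(their gradients are non-zero from the first step, which the test suite
checks).

**Input-prediction regularizer.**  The regularized variants add a linear
head that predicts the next hour's normalized input vector
`x_hat[t+1]`.  Two things happen with it: (1) the mean squared error
`lambda / D * ||x_hat[t] - x_t||^2` is added to the loss, forcing the
hidden state to carry enough information to forecast the inputs; and
(2) the pair `(stop_grad(x_hat[t]), x_t)` joins the feedback input at lag
1, shrinking the 6-hour feedback delay to a single hour for the
input-error channel.  `lambda` defaults to 0.1 and is exposed
prominently: the coefficient is a genuinely free knob of the method, and
0.1 places the penalty on the same scale as the cross-entropy term for
\[0,1\]-normalized features at the start of training.

**Regression variant.**  Instead of the binary label the network
predicts the next-6-hour urine total `Y_t`.  Internally the target is
scaled to `Y_t / (6 w)` — the implied mean rate in mL/kg/h — which keeps
both the regression loss and the feedback inputs O(1) across patients of
different weights; the same scaled pair is fed back at lag 6.  The
binary decision is recovered from the predicted total by
`regression_label()`: positive when the implied rate is strictly below
0.5 mL/kg/h, with risk score `0.5 - rate` used for ranking.  Note the
asymmetry documented (not asserted) in the tests: the regression rule
thresholds a 6-hour *mean*, so it agrees with the all-hours-below
classification label exactly when the rate is constant within the
window and may diverge otherwise.

**Stop-gradient.**  Without intervention, the total loss gradient at a
prediction decomposes as the local term plus a sum of future-loss terms
that flow back through the feedback loop:
`dJ/dy_hat_t = dJ_t/dy_hat_t + sum_i dJ_{t+i}/dy_hat_t`.  The future
terms push `y_hat_t` to be a useful *input* for later steps rather than
an accurate prediction, so backpropagation is truncated exactly where
the lagged prediction (and the predicted input) enter the feedback
network.  The default constants are leaves of the computation graph, not
products of a timestep, so they keep their gradient in both modes.
`gradient_audit()` measures all of this numerically: with the rule on,
the automatic gradient of the summed future losses with respect to
`y_hat_t` is identically zero; with it off, it is non-zero and matches a
central finite difference obtained by perturbing the value where it
enters the feedback network.  Because the forward value still flows in
both modes, the finite-difference cross-check is only meaningful in the
off mode.

**Baselines.**  Plain stacked GRU/LSTM, and variants with single-head
scaled-dot-product self-attention over each layer's per-step outputs
(dimension equal to the layer width).  Attention is causally masked by
default: the evaluation protocol scores every hour of the stay, so
bidirectional context would leak future patient information into the
comparison.  A non-causal switch exists for completeness and is
exercised by a test that demonstrates the leak.

All forward and backward passes are explicit matrix computations written
in R; every variant's hand-derived gradient is verified against central
finite differences to ~1e-10 in the unit tests.  Recurrent layers use
the two-bias-vector gate convention, so a GRU layer with input `i` and
hidden width `h` has `3h(i+h) + 6h` parameters
(`count_parameters()` reports exact per-block counts for
capacity-matched comparisons).  Initial hidden states are zeros and are
not trained; only the feedback defaults are.

## Preprocessing

Irregular event streams are resampled onto a 1-based hourly grid where
hour `t` covers `(t-1, t]`.  Hours containing observations take their
mean (observed mask 1); interior gaps take the inverse-time-distance
weighted average of the nearest observed hour on each side — the
"weighted average of the nearest data points" realized as the unique
two-point scheme, which coincides with linear interpolation — and edges
carry the nearest observation outward.  Outliers are clipped to the
per-feature 1st/99th percentile of the fitting cohort rather than
deleted: deletion would puncture the hourly grid the models require.
Min-max normalization then maps the clipped pool to \[0, 1\]; constant
features map to 0.  Binary intervention flags pass through unscaled.
Statistics are fitted per training fold by default (provenance is
recorded and asserted), with a pooled-cohort switch for literal
whole-cohort normalization at the cost of evaluation leakage.  Static
covariates (age, gender, comorbidity flags) are scaled with the same
machinery and broadcast to every hour; weight is reserved for the
labeling rule and is not a model feature.

## The synthetic cohort generator

Real critical-care extracts are credentialed, so the package ships a
seeded generator whose point is *testability*, not clinical realism.  A
latent renal state `r_t` in \[0, 1\] relaxes toward 1 with half-life
`recovery_halflife` and drops by a random depth in \[0.4, 0.9\] at
injury onsets (per-hour probability `injury_rate`).  Hourly urine is
`max(0, w (0.25 + 1.25 r_t) + noise)`, placing the 0.5 mL/kg/h boundary
exactly at `r = 0.2` in the noiseless limit so label prevalence is
controllable and the task is learnable by construction.  Vitals drift
with `1 - r`; creatinine-like labs track `1 - r` with a 6 h lag and are
drawn at irregular 4–12 h gaps (structural missingness that exercises
imputation); interventions are 0/1 step functions; each stay draws from
an independent substream of `(seed, stay_index)` so cohorts are
reproducible under parallel generation.

Defaults were chosen once, as study conditions: stays of 13–96 h (13 is
the minimum with at least one evaluable step), `injury_rate = 0.03` and
`recovery_halflife = 60` h, which put the positive-label fraction near
8% — inside the 5–15% band typical of ICU AKI incidence and imbalanced
enough to make the reweighted loss matter; urine noise SD 10 mL/h
(≈ 0.13 mL/kg/h for an 80 kg patient) so that hours near the threshold
genuinely flip.  What the generator does *not* emulate: pharmacokinetics,
treatment feedback on the latent state, informative (MNAR) missingness,
unit heterogeneity, or any schema of a real ICU database.  Passing the
benchmark on this cohort therefore shows that the architectures learn a
temporally structured, imbalanced signal under structural missingness —
not that they reach any particular performance on real EHR data.

## Training and evaluation protocol

Weighted cross-entropy (positive weight = negatives/positives on the
training folds), Adam with learning rate 1e-3 and multiplicative decay
0.98 per epoch as library defaults, global gradient-norm clipping at
1.0, dropout 10% between layers and before the heads (off at
evaluation).  Early stopping on a validation split stands in for
"trained until convergence".  Cross-validation splits *stays*, never
time steps; each fold refits normalization statistics on its training
stays.  Metrics — AUC as the tie-aware rank statistic (exactly the
normalized Mann-Whitney U) and F1 at probability 0.5 — are pooled over
all (stay, hour) pairs with `t > 6` and a defined label; per-stay
averaging is available but pooling is the default since the alternative
up-weights short stays.

The packaged benchmark trains 2-layer, 32-unit models on 2,000 simulated
stays with 5-fold cross-validation, 3 training seeds, 3 epochs at
learning rate 3e-3 (batches of 64 length-bucketed stays).  Three epochs
suffice because the cohort's signal is strong by construction; the small
model keeps the whole comparison tractable on one CPU.  The comparison
asserts, at the one-standard-deviation level across seeds, that the
regularized self-correcting model matches or beats the baseline GRU in
pooled AUC and that `lambda = 0.1` does not widen the train/eval AUC
gap relative to `lambda = 0`.  These are directional claims about
ordering, deliberately weaker than point estimates: with three seeds the
SD is a coarse yardstick, and the synthetic task is easier than real
EHR data, which compresses differences between architectures.

## Numerical choices and degenerate inputs

* Probabilities are clamped to `[1e-12, 1 - 1e-12]` inside the
  cross-entropy only; the model outputs themselves are untouched.
* Padded batch positions carry explicit zero loss coefficients; their
  adjoints vanish identically along the backward recursion, so padding
  can never contaminate gradients (checked by the engine-vs-reference
  equality test with mixed stay lengths).
* A training fold whose labels are single-class raises an error rather
  than silently producing a degenerate class weight; a single-class
  *evaluation* fold reports `NA` AUC with a warning instead of being
  skipped.
* Constant features normalize to 0; a feature never observed in the
  fitting cohort is a named error.
* Ties in AUC count one half; F1 is 0 by convention when nothing is
  predicted positive.
* `approx(rule = 2)` performs the interior interpolation and edge carry
  in one pass; single-observation variables become constant columns.

## Known limitations

* The feedback vector is shared across recurrent layers; a
  layer-specific variant is left as a configuration stub because the
  choice cannot be resolved from first principles and the shared form is
  cheaper.
* Imputed urine hours count toward the RIFLE window; the label table
  flags observed hours so stricter analyses can filter on the mask.
* The regression variant's decision rule thresholds a 6-hour mean rate
  and can disagree with the all-hours-below label on non-constant
  windows.
* Stay length is recovered from the last recorded hour when reading
  cohort files; a stay whose final hours contain no events at all would
  be shortened accordingly.
* Pure-R matrix computation is fast enough for the packaged benchmark
  (minutes on one CPU) but is not a platform for hidden sizes in the
  hundreds over tens of thousands of stays.
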