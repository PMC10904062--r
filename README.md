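# akiwarn

Early warning of acute kidney injury (AKI) from hourly ICU time series,
using recurrent networks that **feed their own lagged predictions — and
the later-observed true labels — back into every recurrent layer**.

## The problem and the model

For each hour `t` of an ICU stay the task is to predict whether the
patient will satisfy the urine-output RIFLE criterion over the next six
hours:

```
y_t = 1{ u_s / w < 0.5 mL/kg/h  for all s in (t, t+6] }
```

with `u_s` the hourly urine output (mL/h) and `w` the body weight (kg).
Because `y_t` only becomes observable at `t + 6`, a forward-running
model can legitimately consume the pair `(ŷ_{t-6}, y_{t-6})` at step `t`
— its own six-hour-old prediction next to the truth.  The
self-correcting architecture passes that pair through a small
feedforward *feedback network* whose output is concatenated onto the
input of every GRU/LSTM layer; for `t ≤ 6`, trained default constants
stand in.  Two refinements complete the family:

* **Input-prediction regularizer** — an auxiliary head predicts the next
  input vector `x̂_{t+1}`; its MSE (coefficient `λ`) joins the loss and
  the pair `(x̂_t, x_t)` is fed back at lag 1.
* **Stop-gradient** — the total-loss gradient at a prediction decomposes
  as `∂J/∂ŷ_t = ∂J_t/∂ŷ_t + Σ_i ∂J_{t+i}/∂ŷ_t`; the future terms enter
  through the feedback loop and are severed exactly where `ŷ` (and `x̂`)
  enter the feedback network, so each prediction is trained to be
  accurate rather than to be a convenient input for later steps.
* A **regression variant** predicts the next-6-hour urine total and
  recovers the binary decision from the implied mean rate.

Baselines (stacked GRU/LSTM, with optional causally masked
self-attention), the RIFLE labeler, hourly-grid preprocessing with
inverse-distance imputation and per-fold min-max normalization, weighted
cross-entropy, Adam with gradient clipping, stay-level 5-fold
cross-validation, and a gradient-level audit of the stop-gradient rule
are all included.  Every forward/backward pass is explicit matrix code
(no deep-learning runtime); all gradients are finite-difference checked
in the test suite.

Real ICU extracts (MIMIC-III, eICU) are credentialed, so the package
ships a seeded synthetic cohort generator with latent renal
injury/recovery dynamics that makes the entire pipeline trainable and
testable offline.

## Worked example

```r
library(akiwarn)

cohort <- build_cohort(simulate_cohort(sim_config(n_stays = 300, seed = 42)))
round(mean(unlist(lapply(cohort$labels, `[[`, "y")), na.rm = TRUE), 3)
#> [1] 0.065

feat_dim <- nrow(aki_variables()) + length(aki_static_feature_names(25))
configs <- list(
  baseline            = model_config(feat_dim, variant = "baseline",
                                     n_layers = 2, hidden_size = 32),
  self_correcting_reg = model_config(feat_dim, variant = "self_correcting_reg",
                                     n_layers = 2, hidden_size = 32, lambda = 0.1))
tcfg <- train_config(learning_rate = 3e-3, epochs = 3, batch_size = 64,
                     folds = 5, val_fraction = 0, seed = 1)
report <- compare_models(cohort, configs, tcfg, n_seeds = 1)
report$runs[, c("model", "auc", "f1", "gap")]
#>                 model       auc        f1        gap
#> 1            baseline 0.8085573 0.2690180 0.01248384
#> 2 self_correcting_reg 0.8062951 0.2817856 0.01454287
```

Roughly 7% of evaluable hours are AKI-positive, so AUC is pooled over
all (stay, hour) pairs with `t > 6` and F1 uses the reweighted-loss
model at threshold 0.5.  On a cohort this small the two architectures
sit within noise of each other (the feedback mechanism has ~240 training
stays to learn from); the packaged benchmark in the test suite — 2,000
stays, 5-fold cross-validation, 3 seeds — is where the ordering between
the regularized self-correcting model and the baseline is actually
asserted.  The stop-gradient rule can be audited directly:

```r
aud <- gradient_audit(model_config(5, variant = "self_correcting_reg",
                                   n_layers = 1, hidden_size = 4,
                                   dropout_rate = 0, lag = 2),
                      T_hours = 8, seed = 7)
c(on = aud$grad_future_on, off = aud$grad_future_off, fd_err = aud$abs_err_fd)
#>           on          off       fd_err 
#> 0.000000e+00 4.989705e-03 3.000276e-12
```

With the rule on, future losses contribute exactly zero gradient to a
past prediction; with it off they do not, and the automatic gradient
matches a central finite difference.

A command-line wrapper for the whole pipeline lives at
`inst/cli/akiwarn` (`simulate`, `prepare`, `train`, `evaluate`,
`compare`, `audit-gradients`), writing artifacts plus digest manifests
for byte-level reproducibility.

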