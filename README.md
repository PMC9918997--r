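# sjrfest

Continuous estimation of the three-dimensional shoulder-joint reaction
force (SJRF) during wheelchair-related activities of daily living, from
wearable sensors: five inertial measurement units (tri-axial accelerometer
and gyroscope, 128 Hz) on the lower right arm, upper right arm, thorax,
wheelchair frame and wheel, plus surface EMG of the biceps long head and
medial deltoid (1024 Hz).

Shoulder overuse is a central clinical problem for manual wheelchair
users, and the three risk factors — magnitude, frequency and duration of
joint load — can only be characterized outside the laboratory if joint
load can be estimated without motion capture. `sjrfest` implements the
full estimation methodology for researchers in wearable-sensor
biomechanics:

* a **synthetic wheelchair-activity cohort generator** (10 participants ×
  8 activities split into 19 subtrials, multi-rate streams with hidden
  clock offsets, known nonlinear force generation) so the pipeline is
  fully testable without laboratory data;
* the **signal-processing chain**: zero-phase 4th-order Butterworth
  filtering (IMU low-pass 10 Hz; EMG high-pass 20 Hz, rectification,
  envelope low-pass 3 Hz, submaximal-contraction normalization; SJRF
  low-pass 4 Hz), cross-correlation stream synchronization on a fiducial
  burst, and resampling of everything onto one shared 25 Hz grid;
* **cross-validation designs**: leave-one-trial-out (LOTO,
  subject-specific) and leave-one-subject-out (LOSO, generalizable), with
  train-only standardization (mean / unit variance);
* **sequence regressors**: a bidirectional LSTM (3 layers × 128 units per
  direction, dropout 0.37, ReLU) and a per-timestep network (dense
  250/100 + ReLU), trained with MSE, Adam, whole-sequence batches and
  early stopping (patience 6, max 200 epochs, best-epoch restore),
  repeated over seeded re-initializations;
* **evaluation**: Pearson correlation and range-normalized RMSE on the
  total force `Ftot = sqrt(Fx^2 + Fy^2 + Fz^2)`, aggregated per activity
  and per participant; shoulder-load profiles (25 N histograms of Ftot)
  compared by the Swain–Ballard intersection
  `I(y, ŷ) = Σ min(yᵢ, ŷᵢ) / Σ yᵢ`;
* an **experiment orchestrator** reproducing the three-step model
  selection (validation strategy → sensor setup → architecture) and the
  unseen-activity probe for an orphaned weight-relief subtrial.

The biLSTM and the training loop are implemented in the package itself
(RcppArmadillo kernel for the LSTM recursions; gradients verified against
finite differences in the test suite).

## Worked example

Generate a small cohort, train a subject-specific biLSTM on one
leave-one-trial-out fold, and evaluate the held-out subtrial:

```r
library(sjrfest)

cohort  <- generate_cohort(n_participants = 2, seed = 42,
                           duration_scale = 0.3, n_exclusions = 0)
samples <- build_cohort_samples(cohort, sensor_setup("sparse"))
fold    <- make_loto_folds(cohort$manifest, participant_id = 1)[[3]]

model <- fit_fold(fold, samples,
                  sjrf_config("bilstm", input_width = 20,
                              bilstm_layers = 1, bilstm_units = 32,
                              dropout = 0.1, max_epochs = 100, patience = 8))
print(model)
#> SJRF sequence regressor: biLSTM (1 layers x 32 units/direction, dropout 0.10)
#>   inputs: 20 channels at 25 Hz -> 3 force components
#>   parameters: 13,763
#>   trained 100 epoch(s), best validation loss at epoch 100
#>   final train MSE 0.0499, best val MSE 0.2299 (standardized)

test <- samples[[fold$test]]
pred <- predict(model, test)
pearson(compute_ftot(pred), compute_ftot(test$Y))
#> [1] 0.9867876
rrmse(compute_ftot(pred), compute_ftot(test$Y))
#> [1] 5.462879
```

The printed numbers mean: the network maps the 20 sparse-setup channels to
the 3 force components with ~13.8k parameters; on the held-out propulsion
subtrial the predicted total force tracks the ground truth with a Pearson
correlation of 0.99 and an RMSE under 6% of the ground-truth force range.
(Exact values depend on platform floating-point behaviour; regenerate with
the code above.)

The full stepwise experiment and report:

```r
exp <- run_experiment(cohort, model_opts = list(
  bilstm_layers = 1, bilstm_units = 16, max_epochs = 30, patience = 5),
  n_iterations = 2, seed = 1)
final_report(exp)
```

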