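# crgcn

Emotion classification from multichannel EEG with a graph convolutional
network whose channel graph fuses **electrode-distance topology** with
**functional connectivity**.

## The problem

EEG electrodes are irregularly placed on the scalp, so inter-channel
structure is naturally a graph, not a grid. Distance-based channel graphs
capture local relationships but miss the strong couplings between distant
electrodes that shared cortical sources induce. `crgcn` classifies binary
valence/arousal from DEAP-layout recordings (40 trials × 32 channels ×
8064 samples at 128 Hz; 3 s baseline + 60 s stimulus; ratings 1–9,
binarized at 5) by combining both relationship types in one adjacency
matrix.

## The method

Per 6 s sliding window (stride 3 s, 19 windows per trial after baseline
calibration), each channel contributes the z-scored mean power spectral
density of the theta, alpha, beta and gamma bands as node features
(Welch estimator). The channel graph is

- topology: `A_ij = min(1, δ / d_ij²)`, with `δ` calibrated so that ≈20%
  of off-diagonal entries exceed the nonignorable cutoff 0.1,
- connectivity: `B_ij = p_ij` if `|p_ij| > λ` (Pearson correlation of
  channel feature vectors, λ = 0.98), else 0,
- fused: `C = A + B`.

From `C` the normalized Laplacian `L = I − D^(−1/2) C D^(−1/2)` is formed
and node features are filtered with a K-order Chebyshev polynomial of the
scaled Laplacian,

```
y = Σ_{k=0}^{K−1} θ_k T_k(L̃) x ,   T_k(x) = 2x T_{k−1}(x) − T_{k−2}(x),
```

followed by ReLU, dropout, a dense softmax head, and training with Adam on
cross-entropy + α‖w‖² (K = 2, dropout 0.2, batch 128, η = 5·10⁻⁴).
Accuracy and F1 are reported under random five-fold cross-validation,
subject-dependent or pooled (subject-independent), with the normalizer and
the connectivity matrix fitted per fold on the training split only.

A seeded synthetic generator produces DEAP-shaped data with known class
structure (class-scaled gamma power, distance-decaying noise correlation,
a planted high-correlation channel group, per-channel gain confounds, and
a trial-invariant artifact that baseline calibration must cancel), so the
whole pipeline is testable without any dataset download.

## Worked example

```r
library(crgcn)

# 1 synthetic subject, 12 trials, DEAP layout
cfg <- synth_config(n_subjects = 1, n_trials_per_subject = 12, seed = 5)
ds  <- generate_trialset(cfg, rep(c(0L, 1L), 6))
ds
#> <crgcn_trialset> subject s01: 12 trials x 32 channels x 8064 samples @ 128 Hz (3 s baseline)

# distance graph on the bundled 10-20 montage
m <- default_montage()
delta <- calibrate_delta(m)           # 0.0591877
a <- distance_adjacency(m, delta)
mean(a$adjacency[row(a$adjacency) != col(a$adjacency)] > 0.1)
#> [1] 0.2016129                       # ~20% nonignorable connections

# full pipeline: features -> fused graph -> training -> 2-fold CV
rep <- run_experiment(ds, k = 2,
                      config = model_config(max_epochs = 40,
                                            hidden_width = 16, seed = 1),
                      seed = 2)
rep
#> <crgcn_eval_report> valence, subject-independent, adjacency = fused (lambda = 0.98), normalization on
#>   accuracy mean 1.0000 [1.0000, 1.0000]  F1 mean 1.0000
```

The retention fraction says the calibrated distance graph keeps 200 of the
992 off-diagonal entries above the 0.1 cutoff — the smallest achievable
step at or above 20%. The perfect cross-validated accuracy reflects the
default generator's strong planted gamma effect (class-1 trials double
their gamma amplitude); harder settings (`band_effect`, `noise_amp`,
`channel_gain_sd`) are how the ablation tests probe the regime below
ceiling.

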