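# skelgait

Person identification from Kinect-style 3D skeleton gait, end to end:
gait-cycle segmentation from the inter-ankle distance signal, per-cycle
`Nf × Nb × 3` joint-coordinate tensors, a compact residual convolutional
network with global average pooling that classifies variable-length cycles
without resampling, subject-wise five-fold cross-validation, and the full
biometric metric suite (accuracy, macro precision/recall/F-score, CMC,
macro-averaged ROC/nAUC, EER). A parametric synthetic walker makes every
stage reproducible without external data.

It is aimed at researchers in behavioral biometrics and human movement
analysis who want a transparent, fully scriptable reference pipeline for
skeleton-based gait recognition in R.

## Method

A walking skeleton stream (Nb = 20 joints at 30 fps) yields the signal
d(t) = ‖ankle_L(t) − ankle_R(t)‖₂, which peaks twice per gait cycle. After
a moving-average and a median filter (both window 5), a complete gait
cycle is the span of three consecutive local maxima of d. Each cycle
becomes a tensor X ∈ ℝ^(Nf×Nb×3) — an exact copy of the tracked
coordinates, with Nf varying freely across cycles and subjects.

The classifier is

    conv 3×3×16 – BN – ReLU
    → residual stages [3×3, 16, s1] [3×3, 32, s2] [3×3, 32, s1]
                      [3×3, 64, s2] [3×3, 64, s1]
    → global average pooling → dense P → softmax

where a stride-1 stage uses an identity skip and a stride-2 stage halves
both spatial axes and projects its shortcut through a 1×1 convolution +
BN. Global average pooling maps any Nf to a 64-dimensional embedding, so
cycles are never padded or resampled. With a 30-class head the network has
171,886 trainable and 1,056 non-trainable parameters; `param_count()`
derives both in closed form from the configuration. Training minimizes
categorical cross-entropy with Adam (SGD and RMSProp are available for the
ablation harness); batches mix cycle lengths by splitting each batch into
equal-Nf compute groups that share one set of batch-norm statistics. The
entire network — forward, backward, optimizers — is implemented in R on
BLAS matrix products and is verified against finite-difference gradients
and a naive-convolution oracle in the test suite.

## Worked example

```r
library(skelgait)

walks <- simulate_population(n_subjects = 4, sequences_per_subject = 5,
                             duration = 8, seed = 42)
dataset <- assemble_dataset(walks)
print(dataset)
#> <gait_dataset: 149 cycles, 4 subjects, Nf in [28, 34]>
#> # A tibble: 149 x 7
#>    subject_id sequence_id start_frame end_frame    nf label tensor
#>  1 S01        walk1                12        39    28     0 <gat_tnsr[...]>
#>  2 S01        walk1                39        66    28     0 <gat_tnsr[...]>
#> # ...

cv <- cross_validate(dataset, k = 5, optimizer = "adam", batch_size = 32,
                     epochs = 10, seed = 42)
print(cv)
#> <gait_cv: 5-fold, adam, batch 32, 10 epochs>
#>   mean accuracy 0.8857  precision 0.8993  recall 0.8821  F 0.8829
#>   rank-1 0.8859  nAUC 0.9692  EER 0.0839
```

The 149 cycles are all gait cycles segmented from 20 recordings; `nf` is
each cycle's length in frames (it tracks each subject's stride period).
Fold *f* trains on four recordings per subject and identifies the cycles
of the held-out fifth, so the mean accuracy 0.886 is the probability that
a single unseen gait cycle is attributed to the right person among P = 4;
rank-1 of the CMC equals it by construction. nAUC is the area under the
macro-averaged one-vs-rest ROC (1 = perfect separability) and the EER of
0.084 is the operating point where false accepts equal false rejects.
At this small training depth the model is not yet converged — the default
scaled experiment below trains longer and reaches 0.95 on 10 subjects.

`autoplot(cv, "cmc")`, `autoplot(cv, "roc")` and `autoplot(cv, "loss")`
draw the corresponding curves; `tidy(cv)` and `glance(cv)` return the
per-fold and summary metric tables. `compare_optimizers()`,
`compare_batch_sizes()` and `compare_pooling()` rerun the experiment along
one axis and tabulate the results. A command-line front end with
`simulate` / `segment` / `tensors` / `train` / `evaluate` / `run`
subcommands is installed at `inst/scripts/skelgait.R`.

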