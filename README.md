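# pcamseg

Segmentation of retinal blood vessels in colour fundus photographs with a
U-shaped encoder–decoder that adds two components on top of the standard
U-Net skeleton:

* **PCAM** — a *pyramid channel attention module*. Spatial pyramid pooling
  (non-overlapping max pooling with windows 2, 3, 5, 6, each bilinearly
  upsampled back to the input size) builds a multi-scale description set
  `S` of the stage's feature map `F`; a shared two-layer MLP gates `S` per
  channel,

  `Mc(S) = sigmoid( W1 f(W0 avgpool(S)) + W1 f(W0 maxpool(S)) )`,

  and the module emits `[F, S ⊙ Mc(S)]`, fused back to the input channel
  count by a pre-activated 1×1 convolution. The gates up-weight channels
  carrying vessel structure across scales, which is what recovers thin
  distal vessels.

* **PRDC** — a *pre-activated residual DropBlock convolution block*,
  `y = x + F(x)` with branch `[BN → ReLU → conv → DropBlock] × 2`.
  DropBlock zeroes contiguous `β × β` squares at the seed rate
  `ρ = (1 − keep_prob)·ωh / (β²(ω−β+1)(h−β+1))`, a structured dropout
  that regularises convolutional maps without shredding their continuity
  (`β = 1` recovers ordinary dropout).

The package is aimed at method study at desk scale: every forward *and*
backward pass is implemented explicitly (small C++ kernels for the hot
loops), so the whole network is trainable on CPU and verifiable against
finite differences. Around the network it provides the full experimental
harness: a synthetic vessel-phantom generator with pixel-exact ground
truth, loaders for DRIVE/CHASE_DB1/STARE-style layouts with
field-of-view (FoV) mask estimation, patch-based inference with overlap
averaging, the standard metric suite (IOU, Acc, Sen, Spe, F1, counted
inside the FoV), training with Adam, and a four-variant ablation harness
(`baseline`, `baseline+PCAM`, `baseline+PRDC`, `baseline+PCAM+PRDC`).

## Worked example

Train a small model on synthetic phantoms and evaluate held-out phantoms:

```r
library(pcamseg)

train_set <- generate_dataset(30, phantom_params(), seed = 101)
test_set  <- generate_dataset(6,  phantom_params(), seed = 901)

model <- build_model(model_config(depth = 2, base_channels = 8), seed = 1)
n_parameters(model)
#> [1] 31743

fit <- train(model, train_set,
             train_config(epochs = 5, batch_size = 2, lr = 2e-3,
                          loss = "bce+dice", seed = 1))
fit$history
#>   epoch      loss
#> 1     1 1.1716108
#> 2     2 0.8215039
#> 3     3 0.6507256
#> 4     4 0.5212785
#> 5     5 0.4420779

ev <- evaluate_model(fit$model, test_set)
round(as.data.frame(ev$aggregate), 4)
#>      acc    sen    spe     f1    iou
#> 1 0.9614 0.8994 0.9683 0.8235 0.6999
```

The loss falls steadily over the five epochs and the held-out phantoms are
segmented at IOU 0.70 — far above the ≈ 0.1 an all-positive predictor
would score under the phantoms' 5–15 % vessel fraction, i.e. the model has
learned the curvilinear structure rather than the class prior. Sensitivity
(vessel recall) 0.90 with specificity 0.97 shows the expected trade-off:
the attention-equipped model favours catching thin vessels over suppressing
the last false positives.

Metric bookkeeping follows the standard confusion identities, e.g.

```r
r <- metrics(confusion(pred, gt))
c(r$iou, r$f1, f1_from_iou(r$iou))
#> [1] 0.8000 0.8889 0.8889   # F1 = 2·IOU/(1+IOU) from one confusion table
```

The same functions drive `run_ablation()`, which trains the four variants
under one shared seed and data stream and emits an
`Acc / Sen / Spe / F1 / IOU` table, one row per variant.

A thin command-line front end covers the same workflow
(`synthesize`, `train`, `predict`, `evaluate`, `ablate`):

```sh
Rscript inst/cli/pcamseg.R synthesize --n 6 --out data/ --seed 1
Rscript inst/cli/pcamseg.R train --config config.yaml
```

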