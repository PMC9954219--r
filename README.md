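# mbinet — Self-ONN classification of reconstructed microwave brain images

`mbinet` implements **self-organized operational neural networks
(Self-ONNs)** — convolutional networks whose neurons apply a learned
polynomial *nodal operator* instead of a fixed linear kernel product — and
the lightweight **MBINet** classifier built from them for six-class tumor
screening on reconstructed microwave brain (RMB) images. It is aimed at
researchers who want a compact, fully inspectable implementation of the
operational-layer idea in R, together with the complete evaluation protocol
around it: preprocessing, deterministic augmentation, stratified five-fold
splitting, training with early stopping, weighted multiclass metrics and
ROC/AUC. A seeded synthetic head-phantom generator makes the whole pipeline
runnable and testable without access to clinical data.

## The model

A standard convolution computes, for output neuron k of layer L,

    o_k = b_k + sum_i  w_ki * y_i

where `*` is cross-correlation over a 3×3 window. An operational layer
generalizes the per-connection product to a learned Q-th order polynomial
(a truncated Taylor expansion around a):

    Psi(w_ki, y_i) = sum_{q=1..Q}  w_ki^(q) (y_i - a)^q
    o_k = b_k + sum_i Psi(w_ki, y_i)

Every kernel element therefore carries Q trainable coefficients; `Q = 1`
reduces *exactly* to an ordinary convolution layer, which is how the
"vanilla CNN" baselines in the model zoo are built. Activations are `tanh`
(range [-1, 1]), which pins the expansion point to `a = 0`. The constant
Taylor term is absorbed into the layer bias.

**MBINet** stacks seven such layers (channels 8, 8, 8, 8, 8, 16, 32, all
3×3, same-padded, Q = 3) with 2×2 stride-2 max pools after layers 1, 3, 5
and 7 and a final 3×3 stride-3 pool, so a 224×224×3 input is traced
224 → 112 → 56 → 28 → 14 → 4 into a 512-feature flatten, followed by a
dense 512 → 6 softmax head: 28,006 trainable parameters in total. Training
uses Adam (lr 5e-4, batch 16, ≤30 epochs), reduce-on-plateau (×0.2) and
patience-5 early stopping on validation loss. Forward and backward passes
for the operational layers are implemented in C++ (RcppArmadillo,
im2col + GEMM over the power-stacked input); everything is differentiated
by hand-written backpropagation and verified against central finite
differences in the test suite.

## Worked example

Train MBINet (scaled to 64×64 input) on synthetic phantoms — 60 training,
15 validation and 20 test images per class — in about two minutes on one
CPU:

```r
library(mbinet)

params   <- phantom_params(image_size = 64)
train_ds <- generate_dataset(60, params, seed = 11)
val_ds   <- generate_dataset(15, params, seed = 12)
test_ds  <- generate_dataset(20, params, seed = 13)

to_xy <- function(ds) {
  norm <- lapply(ds$images, zscore_normalize)
  list(x = images_to_batch(norm), y = ds$labels)
}
tr <- to_xy(train_ds); va <- to_xy(val_ds); te <- to_xy(test_ds)

set.seed(100)
model <- build_mbinet(mbinet_config(input_size = c(64, 64, 3)))
model
#> MBINet: Self-ONN classifier (Q = 3)
#>   input 64x64x3, 6 classes, flatten length 32
#>   7 operational layers, 1 dense layers, 25126 trainable parameters

fit <- train_model(model,
                   list(x_train = tr$x, y_train = tr$y,
                        x_val = va$x, y_val = va$y),
                   hyperparams(seed = 101))
fit
#> MBINet fit: 30 epoch(s), stopped on max_epochs
#>   best val loss 0.2736; last epoch val acc 0.978

ev <- evaluate_model(fit, te$x, te$y)
ev$metrics
#> overall accuracy: 97.50%
#> weighted metrics (%):
#>    accuracy   precision      recall specificity          f1
#>       99.17       97.58       97.50       99.50       97.52
#> per class:
#>  class support accuracy precision recall specificity     f1
#>     NT      20   100.00    100.00    100         100 100.00
#>     BT      20   100.00    100.00    100         100 100.00
#>     MT      20   100.00    100.00    100         100 100.00
#>    BBT      20    99.17    100.00     95         100  97.44
#>    MMT      20    98.33     95.00     95          99  95.00
#>    BMT      20    97.50     90.48     95          98  92.68
ev$roc$auc
#> [1] 0.9992778
```

The overall accuracy is the fraction of the 120 held-out phantoms assigned
to the right class; the weighted columns are support-weighted one-vs-rest
metrics, and `ev$roc$auc` is the micro-averaged one-vs-rest AUC. Exact
numbers shift by a few points with other seeds (e.g. seeds 1/2/3 with
initialization 42/43 give 85% accuracy, AUC 0.987): six-way separation of
double-tumor classes from 360 training images is a genuinely stochastic
outcome at this scale.

The same run is available from a shell through the CLI shim:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/mbinet.R", package = "mbinet"))')
Rscript $CLI synth    --per-class 10 --input-size 64 --seed 1 --out data/demo
Rscript $CLI crossval --paper-counts --dry-run       # split arithmetic only
Rscript $CLI crossval --per-class 10 --input-size 64 --epochs 2 \
                      --model Self-ONN4L --max-folds 1 --seed 7 --out runs/demo
```

Subcommands: `synth`, `split`, `train`, `evaluate`, `crossval`, `report`;
exit codes 0 (ok), 2 (config error), 3 (data error), 4 (divergence). Every
run directory receives the resolved configuration, the fold plan, per-fold
metrics/confusion/ROC/history CSVs, `metrics.json`, checkpoints and a log.

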