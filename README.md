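# restransnet

Noninvasive prediction of PD-1 expression status from CT lesion patches,
with an end-to-end R implementation of **ResTransNet** — a hybrid residual
convolutional / transformer network — and the surrounding clinical
evaluation toolkit.

## The problem

PD-1 (programmed cell death protein 1) status determines which
hepatocellular-carcinoma patients are likely to respond to checkpoint
blockade therapy, but assessing it requires invasive biopsy and
immunohistochemistry. ResTransNet instead classifies 128×128 grayscale
tumor-centered patches from portal-vein-phase contrast CT. The package is
aimed at methods researchers who want a fully inspectable, desk-scale
implementation of the model, its class-imbalance strategy, and its
evaluation statistics — including a seeded synthetic CT-lesion cohort
generator that makes every stage testable without patient data.

## The model

A patch `x ∈ [0,1]^{128×128}` passes through:

* three residual convolution blocks (channels 16 → 32 → 64, stride 2
  each, batch norm, projection shortcuts) → feature map `X ∈ R^{64×16×16}`;
* a learned linear patch embedding of the 4×4 patch grid, with a class
  token `x_class` prepended and position embeddings added;
* 12 pre-norm transformer blocks,
  `Z = MSA(LN(X)) + X`, `Y = MLP(LN(Z)) + Z`, with 4-head attention
  `softmax(QKᵀ/√d_k)V`;
* a nonlinear classifier (linear–ReLU–linear) reading only the final
  class-token state `Y⁽⁰⁾`, trained with cross-entropy
  `L = −Σ(y log ŷ + (1−y) log(1−ŷ))`.

Training follows the published recipe (SGD, lr 0.01, momentum 0.9, weight
decay 5e-4, lr ÷10 at epochs 50/100/150) and addresses the ~21% positive
class prevalence by minority oversampling plus a **gradient penalty**: the
flattened per-sample gradients `g_i` are compared pairwise by cosine
similarity `g_i·g_j/(‖g_i‖‖g_j‖)`, and samples participating in any pair
above a threshold ε (near-duplicates created by oversampling) have their
gradients shrunk by λ before aggregation `(1/n) Σ f_i g_i`. Loss
re-weighting (inverse class frequency) is provided as the third strategy.

Evaluation includes ACC/SEN/SPEC, ROC/AUC, decision-curve analysis
(net benefit `TP/N − FP/N·p_t/(1−p_t)`), Mann–Whitney U, and
Kaplan–Meier / log-rank comparison of survival between predicted PD-1
groups.

The forward and backward passes are written in base-R/BLAS linear algebra
with a small set of compiled convolution kernels; no deep-learning
framework is required.

## Worked example

```r
library(restransnet)

## a synthetic cohort: 60 patients, strong planted intratumoral texture
co <- generate_synthetic_cohort(n_patients = 60, images_per_patient = 1,
                                effect_size = 3, survival_link = NULL,
                                seed = 402)
print(co)
#> Synthetic/loaded CT-lesion cohort
#>   60 images, 60 patients, 26.7% PD-1-positive (patient level)
#>   patch size 128 x 128; survival: absent

## fit a reduced network (2 transformer blocks, d = 32) on an 8:2
## patient-level split
fit <- restransnet(co,
  config = rtn_train_config(epochs = 8, batch_size = 24, seed = 402),
  model_config = rtn_model_config(n_blocks = 2, d = 32))
print(fit)
#> ResTransNet classifier
#>   backbone 16/32/64, 2 transformer blocks (d=32, 4 heads); imbalance: gradient_penalty
#>   48 train / 12 test images (48 / 12 patients), 8 epochs
#>   held-out AUC 1.000 (best epoch 4)

summary(fit)
#> Performance at threshold 0.50 (best epoch 4)
#>         ACC   SEN SPEC   AUC
#> train 0.771 0.214    1 0.884
#> test  0.917 0.500    1 1.000
```

The held-out AUC of 1.000 says the reduced network has fully ranked the
12 test patients by their planted texture signal after 8 epochs; the
accuracy and sensitivity at the fixed 0.5 threshold lag behind the AUC
because the score distribution is not yet calibrated around 0.5 (training
is short and the train-mode scores feeding the train row are noisier
still). `plot(fit)` shows the loss and AUC trajectories;
`predict(fit, newdata)`, `residuals(fit)` and `simulate(fit)` behave as
for any classed R model fit.

Interpretability helpers mirror the published visualizations:
`feature_maps(fit, img)` extracts per-stage convolution activations, and
`class_activation_map(fit, img)` renders the last transformer block's
class-token attention as a 128×128 heatmap.

A thin command-line wrapper over these functions ships in
`inst/scripts/restransnet-cli.R` with `simulate`, `train`, `evaluate` and
`explain` subcommands.

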