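# spatialbyol

Self-supervised representation learning for retinal OCT B-scans, with a
spatially-aware twist, and a complete desk-scale pipeline for classifying
**DRIL** — disorganization of the retinal inner layers, an optical
coherence tomography biomarker of diabetic macular edema whose boundaries
between the inner retinal layers cannot be distinguished over a horizontal
extent of the scan.

The package is aimed at researchers who want to (a) pretrain a
convolutional encoder on unlabeled OCT images without negative pairs,
(b) fine-tune it on a small labeled cohort with a disciplined two-phase
protocol, (c) report the clinical evaluation statistics this literature
expects (confusion-matrix metrics, Cohen's κ inter-observer agreement), and
(d) inspect decisions with Grad-CAM — all of it testable offline thanks to
a synthetic OCT phantom generator. The neural-network layers (convolution,
batch normalization, pooling, backpropagation, AdamW) are implemented in
the package on RcppArmadillo.

## The method

**Spatial BYOL.** Bootstrap Your Own Latent (BYOL) trains an *online*
network to predict a slowly-moving *target* network's representation of a
second augmented view, with the target updated only by an exponential
moving average, ξ ← τξ + (1−τ)θ with τ = 0.996. The per-pair loss is the
cosine distance ℓ(a,b) = 2 − 2·a·b/(‖a‖‖b‖) ∈ [0,4].

Standard BYOL pools the deepest feature map and loses all spatial
structure. Here the encoder is tapped at two depths of a ResNet-50-style
backbone — s₁ ∈ R^(B×1024×14×14) at stride 16 and s₂ ∈ R^(B×2048×7×7) at
stride 32 for 224×224 input — and two objectives are combined:

* a **global loss** on the pooled s₂ through the usual projector/predictor
  MLPs, L_global = ½[ℓ(p₁ᵍ, z₂ᵍ) + ℓ(p₂ᵍ, z₁ᵍ)];
* a **spatial loss** on s₁ through convolutional heads that preserve the
  14×14 grid: the cosine distance between the 128-dimensional online
  prediction and target projection vectors at *each* of the 196 locations,
  averaged over locations and symmetrized over views;
* the hybrid objective L_hybrid = 0.5·L_global + 0.5·L_spatial.

Pretraining uses AdamW (3e-4, weight decay 1e-4), batch 64 with gradient
accumulation ×4 (effective batch 256), cosine learning-rate annealing over
100 epochs, gradient clipping at norm 1.0, and early stopping (patience 25,
cap 125 epochs). The full dual-branch model has 73,107,328 parameters.

**Two-phase fine-tuning.** A Kaiming-initialized head (2048→1280→2 with
batch norm and dropout 0.5; 2,627,842 parameters) is trained on the frozen
encoder at lr 1e-3 (phase 1), then everything is unfrozen at a 90%-reduced
rate with ReduceLROnPlateau on validation accuracy (phase 2). The loss is
inverse-frequency-weighted cross-entropy; splits are stratified 80/20 with
a 10% validation carve-out from the training portion.

## Worked example

Inter-observer agreement from a 2×2 table of two graders' DRIL calls
(both-positive, obs1-only, obs2-only, both-negative):

```r
library(spatialbyol)

tab <- agreement_table(409, 16, 11, 387)
cohen_kappa(tab)
#> Cohen's kappa = 0.9343 (95% CI 0.9100-0.9587), observed agreement 96.7% (n = 823)
```

κ = 0.9343 is "excellent" agreement (well above the 0.81 reliability
threshold): the two graders agree on 96.7% of the 823 scans, and only a
third of the apparent agreement would be expected by chance.

Evaluation of a classifier's predictions, DRIL positive:

```r
y_true <- rep(c("DRIL", "NO_DRIL"), c(86, 78))
y_pred <- c(rep("DRIL", 86), "DRIL", rep("NO_DRIL", 77))
classification_report(y_true, y_pred)
#> Classification report (positive class: DRIL, n = 164)
#>   confusion: TP 86  FN 0  FP 1  TN 77
#>   accuracy 99.39%  sensitivity 100.00%  specificity 98.72%
#>   weighted: precision 99.40%  recall 99.39%  F1 99.39%
```

Zero false negatives (sensitivity 100%) is the clinically important
property here: a missed DRIL costs more than a false alarm that a second
reader can clear.

The full pipeline on synthetic phantoms, desk-scale (a reduced encoder at
64×64; runs in well under a minute on one CPU):

```r
ph <- phantom_batch(100, phantom_config(size = 64), seed = 3)   # 200 images
enc <- build_encoder(blocks = c(1, 1, 1, 1), base_width = 8, seed = 2)
model <- build_ssl_model(enc, proj_hidden = 128, proj_dim = 64,
                         spatial_mid = 64, spatial_dim = 32, seed = 2)
fit <- pretrain(model, ph$images,
                config = list(epochs = 3, batch = 16, accum_steps = 4,
                              size = 64, seed = 11))
tidy(fit)
#> # A tibble: 3 × 5
#>   epoch       lr l_global l_spatial l_hybrid
#>   <int>    <dbl>    <dbl>     <dbl>    <dbl>
#> 1     1 0.0003       2.14      2.01     2.07
#> 2     2 0.000300     2.10      1.94     2.02
#> 3     3 0.000300     2.05      1.87     1.96

ft <- finetune_dril(fit, ph$images, ph$labels,
                    config = list(epochs_phase1 = 10, epochs_phase2 = 10,
                                  size = 64, hidden = 64, batch = 16),
                    seed = 5)
ft$report
#> Classification report (positive class: DRIL, n = 40)
#>   confusion: TP 12  FN 8  FP 4  TN 16
#>   accuracy 70.00%  sensitivity 60.00%  specificity 80.00%
#>   weighted: precision 70.83%  recall 70.00%  F1 69.70%
```

The hybrid loss falls over the three pretraining epochs and the fine-tuned
classifier separates lesioned from clean phantoms at 70% test accuracy —
clearly above the 50% majority baseline for this deliberately tiny run.
`autoplot(fit)`, `autoplot(ft)`, `autoplot(ft$report)` and
`autoplot(agreement_table(...))` give the corresponding figures;
`gradcam(ft$classifier, image)` produces saliency heatmaps.

A command-line interface covering the same pipeline
(`synth | pretrain | finetune | evaluate | gradcam | agreement`) ships as
`inst/cli/spatialbyol`.

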