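# lesionlab

Multi-class classification of pigmented skin-lesion images with a fully
inspectable, desk-scale pipeline: formula-exact image enhancement,
GAN-based class balancing, convolutional-autoencoder feature learning with
reconstruction-error anomaly detection, a soft-margin SVM over a
polynomial or classically simulated quantum fidelity kernel, Grad-CAM
explanations, and confusion-matrix metrics. A synthetic lesion-image
generator makes every stage runnable and testable without any external
data, so the package is aimed at method developers and reviewers who want
each component of this kind of CAD pipeline to be verifiable in isolation.

## The model in brief

Images `x` in [0,1] are enhanced by multi-scale retinex
(`R = Σ_s w_s [log(I+ε) − log(G_σs∗I+ε)]`), gamma correction (`I^γ`),
histogram equalization (`v ↦ round((L−1)·cdf(v))`), unsharp masking
(`I + k(I − G_σ∗I)`) and CLAHE (clipped tile histograms, bilinearly
interpolated mappings). A convolutional autoencoder (3×3 convolutions,
2×2/stride-2 max pooling; mirrored 4× up-sampling decoder, sigmoid output)
is trained on the joint objective

    L = BCE(x, x̂) + CE(labels) + (λ/2)‖W‖²,     λ = 0.01,

with Adam (lr 0.001, batch 32, dropout 0.5). Bottleneck activations are
projected onto leading principal components, rescaled to [0, π], and
classified by a one-vs-rest soft-margin SVM (`argmin ½‖w‖² + CΣξ`) over
either the degree-3 polynomial kernel `(⟨x,z⟩)³` or the fidelity kernel
`K(x,z) = |⟨φ(x), φ(z)⟩|²` of a second-order-expansion feature map
(Hadamard + Pauli-Z/ZZ phase layers, simulated exactly). Minority classes
can first be balanced by per-class GANs trained on the minimax value
function `V(D,G) = E[log D(x)] + E[log(1−D(G(z)))]`. Grad-CAM heatmaps
(`ReLU(Σ_k w̄_k A_k)`, `w̄_k` the spatially averaged logit gradients)
explain individual predictions. See `vignettes/lesionlab-methods.Rmd` for
assumptions, defaults and design rationale.

## Worked example

```r
library(lesionlab)

# a small synthetic dataset: 3 severity classes, 12 images each, 16 px
cfg <- pipeline_config(
  dataset = list(image_size = 16, n_classes = 3,
                 counts_per_class = rep(12L, 3L)),
  enhance = list(clahe_tiles = c(2, 2)),
  cae     = list(epochs = 2, widths = c(4, 8), hidden = 8, batch_size = 8),
  svm     = list(n_components = 4),
  seed = 5, verbose = FALSE
)
report <- run_pipeline(cfg)
report
#> <pipeline_report> validation accuracy 0.8333 (softmax head 0.3333)
#> <metrics_report> accuracy 0.8333 (n = 6)
#>   macro: precision 0.8889, recall 0.8333, specificity 0.9167, F1 0.8222
#> # A tibble: 3 × 6
#>   class support precision recall specificity    f1
#>   <int>   <int>     <dbl>  <dbl>       <dbl> <dbl>
#> 1     0       2     1        0.5        1    0.667
#> 2     1       2     0.667    1          0.75 0.8
#> 3     2       2     1        1          1    1
```

The pipeline generated 36 lesion images, enhanced them, split them 80/20
per class, trained the autoencoder for two epochs, fitted the polynomial
SVM on 4 projected latent components, and classified five of the six
held-out images correctly at this deliberately tiny scale — one faint class-0
lesion is mistaken for class 1, which the per-class recall/precision rows
localize immediately. The undertrained softmax head, reported as a
baseline, is still at chance. `tidy()`, `glance()` and `autoplot()` methods give
per-class tables, one-row summaries and standard plots for the report, the
autoencoder history and Grad-CAM heatmaps.

At the standard benchmark scale (7 classes × 70 images, 64×64 pixels, 10
autoencoder epochs — `benchmark_pipeline(seed = 1)`) the pipeline reaches
validation accuracy 0.97, and a label-permutation control falls to the
1/7 chance level.

A thin command-line front end is installed with the package
(`inst/cli/lesionlab`): `lesionlab fixtures|enhance|run|evaluate ...`.

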