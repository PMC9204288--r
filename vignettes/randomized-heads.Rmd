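---
title: "Randomized network heads on deep image features: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomized network heads on deep image features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(randnn)
```

## The problem and the model

Small two-class medical-imaging datasets (here: brain MRI slices labelled
healthy vs unhealthy, on the order of two hundred images with a ~9:1
class imbalance) are a poor fit for end-to-end deep-network training: a
deep classifier head trained by gradient descent on so few samples
overfits readily. The design implemented by this package separates the
two concerns:

1. **Feature extraction.** A pretrained convolutional backbone has its
   final softmax and classification layers removed and a modified head
   appended — a 128-unit fully connected layer (FC128), ReLU, batch
   normalization, a 2-unit fully connected layer, softmax and a
   classification layer (`build_modified_head()`). The network is
   briefly fine-tuned (4 epochs, mini-batch 10, learning rate $10^{-4}$)
   and the activations of FC128 become the feature vector
   $F \in \mathbb{R}^{128}$ for each image.
2. **Closed-form classification.** Everything after FC128 is discarded
   and replaced by a *randomized neural network*: a single hidden layer
   whose input weights $W \in \mathbb{R}^{V\times n}$ and biases
   $d \in \mathbb{R}^{V}$ are drawn randomly once and **frozen**; only
   the output layer is learned, and it is learned in closed form by the
   Moore–Penrose pseudo-inverse, not by iteration.

With $X = (x_1,\dots,x_N)^{\mathsf T}$ the feature matrix,
$Y$ the one-hot target matrix and
$A_{ij} = s(w_j \cdot x_i + d_j)$, $s(z) = (1+e^{-z})^{-1}$, the three
heads are:

* **Schmidt network (SNN)** — output weights $P$ *and* an output bias
  $q$, solved jointly: $[P; q] = [A \mid \mathbf 1]^{\dagger} Y$
  (`train_snn()`).
* **Extreme learning machine (ELM)** — no output bias:
  $P = A^{\dagger} Y$ (`train_elm()`).
* **Random vector functional link (RVFL)** — direct shortcut links from
  input to output: $p = [X \mid A]^{\dagger} Y$ (`train_rvfl()`).

Prediction is the argmax of the linear scores, ties broken toward the
lowest class index.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `V` (hidden nodes) | 400 | width of the frozen random layer; with $V \ge N$ the head interpolates the training set |
| random weight law | uniform $[-1,1]$ | the literature leaves this open; seeded and documented |
| `minibatch_size` | 10 | fine-tuning batch size (small dataset) |
| `max_epoch` | 4 | deliberately short, against overfitting |
| `learning_rate` | $10^{-4}$ | for a *pretrained* backbone |
| pseudo-inverse cutoff | $10^{-12}\,\sigma_{\max}$ | relative singular-value threshold |
| `ridge` | 0 | optional Tikhonov term for ill-conditioned designs |
| `scale` | off | optional z-scoring of features (deep features are used raw) |

Ambiguities the package had to resolve (each is a deliberate, documented
choice, not an upstream fact):

* **How the SNN bias enters the solve.** We append a ones column to $A$
  and solve for $[P; q]$ jointly. This is the standard Schmidt
  formulation and makes a constant target exactly representable
  ($P = 0$, $q = \text{const}$), which the tests assert.
* **RVFL bias.** The design matrix is exactly $[X \mid A]$ with no ones
  column; `add_bias = TRUE` is available but off by default.
* **Tie-breaking**, **weight distribution**, and **pseudo-inverse
  tolerance** as in the table above.

## Evaluation protocol

Five-fold cross-validation (`kfold_split()`, stratified by default so
every fold keeps the class ratio within one sample — with 20 negatives
in 197 samples each fold holds exactly 4 negatives). Per fold the five
confusion-matrix metrics are computed as percentages
(`compute_metrics()`): accuracy, sensitivity (positive = unhealthy),
specificity, precision, F1. A metric with a zero denominator is
*flagged undefined with a warning*, never silently zero — genuine
"0.00" specificities (TN = 0 with FP > 0) remain computable and
distinct from undefined ones (TN = FP = 0).

Aggregation (`aggregate_folds()`) is the arithmetic mean and the
**population** standard deviation (divisor $k$): that is the only
convention under which the published per-fold tables' `Avr`/`Std` rows
are reproduced exactly from their printed fold values, which the
acceptance suite verifies cell by cell. Two printed cells are
internally inconsistent with their own folds (one F1 average off by
0.01 from rounded-input averaging, and one Std row that matches no
convention); for these the suite asserts the fold-implied values and
the discrepancy is recorded in the project notes. Display rounding is
half-up to two decimals; full precision is kept internally and in JSON
reports. AUC uses the rank (Mann–Whitney) formulation with ties counted
one half.

## The built-in extractor, and what a green test establishes

No deep-learning runtime is assumed (or available) here, so the
pretrained backbone is represented by a contract plus a desk-scale
stand-in, `builtin_toy_extractor()`: 64×64 input, 8 frozen random 5×5
convolutions with ReLU, 4×4 average pooling (8×15×15 maps — the
Grad-CAM tap), then the exact modified head above with FC128 as the
feature tap. `fine_tune()` trains the dense head (FC128, batch-norm
affine, FC2) by explicit backpropagation of the softmax cross-entropy;
the random stem stays frozen. Batch norm uses batch statistics during
training and running statistics (momentum 0.1) at inference.

Because the toy stem is random-initialized rather than pretrained, the
desk-scale test configuration uses a larger learning rate (0.05) and
more epochs than the published operating point — otherwise four epochs
at $10^{-4}$ barely move the head. The package defaults remain the
published values; the desk configuration is a test fixture choice, made
once during development and not tuned against any acceptance outcome.

A green pipeline test therefore establishes: the end-to-end protocol
(fold splitting → fine-tune on training folds only → FC128 features →
closed-form head → held-out metrics → aggregation) is correctly wired,
deterministic per seed, and achieves sane accuracy on separable
synthetic data. It does **not** establish the published headline
accuracy, which depends on an ImageNet-pretrained DenseNet and the
original MRI dataset, both outside this package's scope.

## Synthetic data: the stated world

`generate_images()` emulates the structure the pipeline assumes, not MRI
physics: a centered mid-intensity (0.45) ellipse on a dark (0.05)
background, additive Gaussian noise (sd 0.04) clipped at ±4.5 sd, and
for positives 1–3 bright disks (contrast +0.45) inside the ellipse,
with ground-truth masks kept. Defaults are 177 positives vs 20
negatives at 256×256 — the ~9:1 imbalance and geometry of the target
setting. The noise clip is what makes the separability property exact
("some lesion pixel exceeds tissue mean + 5 sd; no healthy pixel
does"): with unbounded Gaussian noise over ~200 images that statement
would be a coin flip, so the clip is part of the stated world, chosen a
priori. What the generator does *not* model: anatomy, disease subtypes,
intensity inhomogeneity, partial-volume effects — conclusions about
real MRI must not be drawn from green tests here.

`generate_feature_table()` draws two unit-covariance Gaussians whose
means are `class_separation`·√dim apart. Separation 6 is essentially
perfectly separable (a nearest-centroid oracle scores ≥ 99%);
separation 0 is pure noise and cross-validated accuracy must hover
around 50%.

## Numerical choices and degenerate inputs

* Pseudo-inverse via SVD with relative cutoff $10^{-12}$; an optional
  ridge term switches to regularized normal equations.
* The oracle-equivalence property (package residual = independent QR
  solver residual to $10^{-8}$) is asserted on numerically well-posed
  designs only (condition number ≤ $10^8$). Random tiny instances
  occasionally produce effectively rank-deficient designs (κ ~
  $10^{16}$) where the minimum residual is not identifiable in double
  precision and solvers legitimately disagree; such draws are redrawn,
  never used to loosen the tolerance.
* Duplicating a training sample provably leaves the fit unchanged in
  the interpolation regime ($V \ge N$, residual 0); in the strictly
  overdetermined regime duplication reweights the least-squares
  objective and *does* move the minimizer, so the invariant is asserted
  where it holds.
* Bilinear resizing uses align-corners mapping, making preprocessing
  idempotent (resize to own size = identity).
* Grad-CAM: channel weights are spatial gradient means, the map is
  ReLU-ed and divided by its maximum (a zero map stays zero) — this
  matches the single-channel closed form `activation / max(activation)`;
  a min–max shift would not when the activation minimum is positive.
  Normalization happens at map resolution, before upsampling, so an
  upsampled map's maximum may fall slightly below 1.

## Known limitations

* The pretrained-backbone path (`backbone_name = "densenet201"`) is a
  contract only; invoking it without a deep-learning runtime raises an
  informative error. All quantitative claims in this package are about
  the closed-form heads, the protocol and the stand-in extractor.
* Binary classification only; the multi-class generalization of the
  heads is mathematically immediate (one-hot $Y$ already supports it)
  but untested beyond $m = 2$.
* Grad-CAM localization is validated as a *weak* property (mean
  attention inside the lesion exceeds outside, averaged over ≥ 20
  seeded positives), not as a quantitative localization benchmark.
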