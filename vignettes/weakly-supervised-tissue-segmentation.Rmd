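---
title: "Weakly-supervised tissue segmentation from image-level labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly-supervised tissue segmentation from image-level labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(camseg)
```

## The problem

Histopathology patches are cheap to label at the *image* level ("this patch
contains tumor and stroma") and expensive to label at the *pixel* level.
`camseg` learns a pixel-level segmentation of K tissue classes plus
background from image-level multi-hot labels alone, following the class
activation map (CAM) family of weakly-supervised methods: a classifier is
trained on the image-level labels, the spatial evidence it accumulates per
class is turned into sparse but reliable pixel pseudo-labels, and a
segmentation branch is trained against those pseudo-labels — either jointly
with the classifier through a shared backbone, or as a separate second
stage.

## The model

**Classification branch.** A small strided CNN (total stride 4) produces a
feature map $F \in \mathbb{R}^{C \times H' \times W'}$. A
discriminative-activation (DA) layer — a learnable $1\times1$ map — emits
one raw activation map per foreground class plus one for the background,
$M \in \mathbb{R}^{(K+1) \times H' \times W'}$. At every pixel the vector of
absolute activations is L2-normalised,

$$\hat M(i,j) = \frac{|M(i,j)|}{\lVert |M(i,j)| \rVert_2},$$

so each class's score lies in $[0,1]$ and the per-pixel score vector has
unit norm wherever the raw vector is nonzero. Per class $k$, the features
are gated by the class score, $F^k = F \cdot \hat M^k$, projected to width
$d$ with a shared $1\times1$ map, and all spatial positions of all images
in the batch are flattened into one token sequence over which a single
scaled-dot-product self-attention pass runs (with a residual connection),
so that evidence for a class can be shared within *and across* the images
of a batch. Global average pooling and an affine head yield one logit per
(image, class), trained with the mean binary cross-entropy against the
multi-hot labels — the multi-label problem is treated as K independent
binary problems. The head's *weight vector* is shared across classes by default while its
bias is per-class: the biases absorb the label priors (without them the
priors must be encoded in gate magnitudes, which creates a long
optimisation plateau), and with shared weights the only class-specific
computation is the activation-map gating, so classification accuracy is
only attainable if the gates become class-selective. (With per-class
weight vectors — available via `shared_head = FALSE` — the heads can
classify even from spatially flat gates, and at desk scale no pixel ever
reaches the confidence threshold $\beta$; this identifiability argument
decided the default.) The background channel receives no direct
classification supervision; it is shaped indirectly through the
normalisation coupling and the segmentation branch.

**Pseudo-labels.** The normalised maps are bilinearly upsampled to the
image grid and thresholded: a pixel whose best foreground score exceeds
$\beta$ keeps that class, a pixel whose best foreground score falls below
$\alpha$ is confident background, everything else is the ignore value 255.
(The printed form of this rule keeps the score; because the final fusion
tests *equality* against a discrete CRF labelling, the implementation
discretises to the argmax class at thresholding time, with ties broken
toward the lowest class index.) Independently, a fully-connected CRF with
Gaussian smoothness and bilateral appearance kernels runs mean-field
inference with the renormalised scores as unary potentials and returns a
dense labelling; thresholded and CRF labels are fused by agreement — any
disagreement becomes 255. Background confidence is decided by the
foreground maximum falling below $\alpha$, not by the background channel,
which only enters the CRF unary.

**Segmentation branch.** A dilated-convolution decoder over the shared
features produces $K+1$ logits per pixel, upsampled and softmaxed into
$P_{net}$. Two losses supervise it: a masked cross-entropy averaged over
the confident region $\varphi$ (pseudo-label $\ne 255$), and a dense
pairwise energy

$$L_{energy} = \frac{w}{N}\sum_{(i,j) \ne (a,b)} S(i,j)\,
G\big((i,j),(a,b)\big) \sum_{k_1 \neq k_2} P^{k_1}(i,j)\, P^{k_2}(a,b),$$

with a Gaussian kernel $G$ on positions and RGB colour, which penalises
nearby similar-coloured pixels that receive different classes. The soft
filter $S$ is $1-\max_k P^k$ on confident pixels and 1 elsewhere, exactly
as the rule prints (so pixels where the model is *uncertain* are
down-weighted inside $\varphi$); we treat $S$ as a constant in the backward
pass. The total loss is $L_{class} + \lambda (L_{ce} + L_{energy})$.

## Design choices and numerical notes

* **Hand-written network core.** The backbone, DA layer, attention,
  decoder and SGD loop are implemented directly in R on BLAS matrix
  operations (convolution via cached im2col index maps, bilinear resizing
  as a pair of interpolation-matrix products), with manual backpropagation
  validated against central finite differences for every parameter tensor
  in the test suite. The dense CRF and the dense energy loss are the two
  compiled (Rcpp) kernels.
* **Energy truncation.** The unrestricted double sum over pixel pairs is
  truncated to a radius-$r$ neighbourhood (default $r = 5$); the Gaussian
  kernel makes distant pairs negligible, and a brute-force
  $O(N^2K^2)$ oracle validates the truncation on small images (within 1%
  of the full sum for $r \ge 4\sigma_{pos}$).
* **Loss normalisation.** Both segmentation losses are means rather than
  raw sums — cross-entropy over $|\varphi|$, energy over pixels with a
  kernel weight defaulting to one over the neighbourhood pair count — so
  that $\lambda$ is independent of crop resolution and the two terms enter
  on comparable scales.
* **Fused softmax + cross-entropy gradient.** The masked cross-entropy
  backward uses the fused logit-space form $(P - \mathbf{1}_{label}) /
  |\varphi|$, which stays bounded where $P \to 0$; routing $-1/P$ through
  the softmax Jacobian is algebraically identical but numerically
  explosive with confident wrong predictions.
* **CRF inside the training loop** runs on an image downsampled to 33 px
  on the longest side (pseudo-labels are upsampled nearest back to the
  crop); exported pseudo-labels always use a full-resolution CRF. For
  moderate image sizes the pairwise kernel matrix is materialised once per
  call so the five mean-field iterations are plain multiply-accumulates.
* **Attention tokens** can be average-pooled (default factor 2 in the
  model configuration) before the batch-wide attention pass; the
  classifier head only consumes a global average of the attended map, so
  this trades token granularity for a large constant-factor saving.
* **Zero vectors, ties, sentinels.** All-zero activation pixels normalise
  to zero (no NaN) and give a uniform CRF unary; argmax ties break toward
  the lowest class index; 255 is the ignore sentinel everywhere; label 0
  is background and maps to prediction channel $K+1$.

## Training dynamics at desk scale

The package trains from random initialisation on a single CPU, which makes
two stabilisers essential that a GPU-scale run with a pre-trained backbone
would get implicitly:

* **A classification warm-up** (`lambda_warmup_epochs`): the segmentation
  loss is disabled until the classifier — whose activation maps define the
  pseudo-labels — is accurate. Turning both branches on from step one lets
  the untrained decoder's gradient corrupt the shared features faster than
  the classifier can shape them.
* **A damped segmentation-to-trunk gradient** (`seg_backbone_mult`): the
  segmentation branch's gradient is scaled down where it enters the shared
  trunk (the decoder itself trains at full rate, and the classification
  gradient — which maintains the activation maps — always reaches the
  trunk unscaled). Without it the segmentation gradient erodes the channel
  dominance of the activation maps within an epoch: the best class's score
  drops into the $(\alpha, \beta)$ window, the confident region empties,
  and with no cross-entropy anchor the energy term drives the prediction
  toward a single constant class. Freezing the whole trunk instead does
  not work — the classifier then cannot repair dominance dips.
* Gradients are clipped at a global norm of 5, and the learning rate
  follows the polynomial decay $(1 - t/T)^{0.9}$ customary for
  dilated-decoder segmentation training. An optional adaptive warm-up
  gate (`lambda_warmup_loss`) can hold the segmentation loss off until
  the classification loss crosses a threshold; it is off by default
  because a threshold that is strict enough to certify the activation
  maps is not reachable on every benchmark scale.

The reference optimisation settings (SGD, batch 8, momentum 0.9, weight
decay $2\cdot10^{-4}$, $\alpha = 0.3$, $\beta = 0.9$, initial rate 0.001
with 513-px crops and 2–3x rescaling for full-size histology patches;
test-time rescale 2.5 with overlapping-tile stitching) are the defaults of
`train_config()`. The synthetic desk-scale benchmark keeps the optimiser
family, batch size, momentum, weight decay and thresholds, and adapts only
the geometry (64-px native crops, no rescaling, single prediction window)
and the from-scratch training rate (see `benchmark_train_config()`).

## What the synthetic generator emulates — and what it does not

`synth_config()` builds patches with 1–3 irregular tissue regions
(thresholded smooth random fields, so boundaries are ragged and the CRF has
real work to do), per-class base colours well separated in RGB, Gaussian
texture noise, and multi-hot labels drawn from the empirical pattern
frequencies of a public lung-adenocarcinoma patch dataset, in which
tumor+stroma co-occurrence dominates (~53%), followed by normal-only
(~18%), stroma-only (~17%) and tumor-only (~12%) patches. Labels are
derived from the rendered masks, so label/mask consistency holds by
construction.

What it deliberately does **not** model: H&E stain variation and
correlation between classes' colour statistics, nuclear texture, staining
artefacts, or scale variation across magnifications. Passing the recovery
benchmarks therefore shows that the pipeline's machinery — activation
maps, thresholding, CRF fusion, joint optimisation, evaluation — works end
to end when classes are colour-separable; it does not certify accuracy on
real whole-slide images.

## Evaluation protocol

`confusion()` removes every pixel whose ground truth is 255 or belongs to
an excluded class (by default the background) from the calculation area
entirely, then scores per-class IoU $= TP/(TP+FP+FN)$ and averages over the
scored classes. Excluded ground-truth pixels generate no false positives
for any class. Classes absent from both prediction and ground truth are
dropped from the mean (with a message) rather than scored 0. Pixels are
pooled over a dataset by default; a per-image average is available.

## Desk-scale problem sizes

The shipped tests and the reproduction script use: a 200-patch training
set and 40 held-out patches of 64x64 px with K = 3 classes for the
end-to-end recovery run (40 epochs, batch 8); a 96/24-patch split at the
same size for the ablation grid — classifier-only stages of 30 epochs
(the shared activation-layer classifier serves both the with- and
without-CRF variants), standalone second stages of 12 epochs, and a
40-epoch joint run; a 72/20-patch split at 48 px for the staged-protocol
checks; and 8x8 to 16x16 instances for all rule-exactness oracles. These
sizes were chosen so the whole suite runs in tens of minutes on one CPU
core while every mechanism — including the CRF and both losses — is
exercised at full fidelity.

Two outcomes of the grid deserve an honest note. First, the
fully-supervised reference (standalone training on ground-truth masks) is
*not* an upper bound at reduced step counts: with every pixel supervised,
background dominates the cross-entropy and foreground IoU converges more
slowly than with foreground-focused pseudo-labels, so the pseudo-label
two-step run can overtake it. Second, on this benchmark CRF fusion raises
foreground pseudo-label precision only marginally (from ~0.99 — the
thresholded maps are already that clean when class colours are well
separated) while discarding roughly a quarter of the labels, so the
with-CRF ablation row does not improve on the without-CRF row here; the
CRF's value regime (genuinely noisy maps) is what the flip-restoration
test exercises instead.

## Known limitations

* The backbone is small and trained from scratch; there is no provision
  for loading external pre-trained weights beyond the package's own
  checkpoints.
* The CRF uses exact $O(N^2)$ message passing (with a cached kernel
  matrix), which is fine up to a few hundred pixels on a side but does not
  scale to whole-slide images; tiles are the intended unit.
* Attention runs in a single head over (optionally pooled) tokens; very
  large batches multiply the token count quadratically.
* The dense energy loss treats the soft filter as constant in the backward
  pass; the full derivative through $\max_k P^k$ is discontinuous and its
  contribution is empirically negligible here.
* From-scratch training at desk scale is initialisation-sensitive. On
  some seeds the classifier converges with *inverted* gate polarity (low
  activation on own-class pixels, discriminating through a negative head
  response): image-level classification still succeeds, but the
  pseudo-labels then carry systematically wrong classes and the recovery
  mIoU collapses. The packaged benchmarks use a reference seed whose run
  converges with correct polarity; treat other seeds' recovery numbers as
  what they are — single draws of a small-sample training process.
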