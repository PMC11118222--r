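---
title: "Mis-seg-focused losses and two-stage training: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mis-seg-focused losses and two-stage training: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msfseg)
```

## The problem

Multi-label 3D tissue segmentation — brain MRI is the motivating case — has
to separate adjacent and nested structures (cerebrospinal fluid, grey matter,
white matter, small structures such as the hippocampus) whose image
intensities overlap. A network trained with a *global* objective, summed over
every voxel, spends most of its capacity on the easy interior of each tissue;
the stubborn errors concentrate along ambiguous boundaries and in small
structures, and the global loss barely feels them. `msfseg` implements a
remedy: after a coarse global stage, explicitly extract the voxels the model
currently gets wrong, and add a second loss term evaluated only there, so the
optimizer is forced to spend gradient on its own mistakes.

## Mis-segmentation regions

Let $y$ be the ground-truth label map and $y'$ the argmax-decoded prediction,
both one-hot encoded into per-label masks $y_n$, $y'_n$, $n = 1..N$. The
per-label error region is the symmetric difference

$$M_n = (y_n \cup y'_n) - (y_n \cap y'_n),$$

i.e. the voxels where exactly one of the two masks is set. Each $M_n$ is
dilated $d$ times with an elementary structuring element to give $Md_n$
(`dilate_region`), and the dilated regions are superimposed into one global
error mask $Md = \sum_n Md_n$ (`merge_regions`). Two conventions are fixed
here:

* **Structuring element.** The elementary element is the 6-connected
  (face-adjacent) cross, applied `factor` times, so the dilation factor reads
  as a city-block radius in voxels. A 26-connected cube is available via
  `connectivity = 26`. Dilation is performed in voxel space; anisotropic
  spacing is deliberately ignored (only the HD95 metric consumes spacing).
* **Clamping the sum.** The superposition is clamped to a binary mask. $Md$
  is used multiplicatively ($\hat{y} = Md \odot y$), where a voxel counted
  twice would be meaningless.

The default dilation factor is 2, the best-performing setting in the
method's ablation; dilation gives the masked loss local context around each
error voxel and stops the refinement stage from fixating on single-voxel
noise. Background (label 0) participates like any other label by default
(`include_background = FALSE` excludes it).

## The compound loss and deep supervision

The segmentation objective is a compound soft-Dice + binary-cross-entropy
loss applied at `dn` decoder resolutions (deep supervision):

$$L(y, y') = \sum_{j=1}^{dn} a_j \left[ L_{Dice}(y_j, y'_j)
  + \omega\, L_{CE}(y_j, y'_j) \right],
\qquad a_j = \frac{2^{-(j-1)}}{\sum_{k=1}^{dn} 2^{-(k-1)}},$$

with $j = 1$ the full-resolution output; each coarser level receives half
the previous weight and the weights sum to one (`ds_weights(3)` is exactly
$4/7, 2/7, 1/7$). The Dice term uses the printed sign convention

$$L_{Dice} = \frac{-2 \sum_i y_i y'_i}{\sum_i y_i + \sum_i y'_i + \epsilon},$$

so $-1$ is perfect and $0$ total disagreement; sums run jointly over voxels
and channels (one global ratio; a per-channel-mean variant is available via
`channel_mean = TRUE`, which changes the reported value but not the training
gradient, which always uses the pooled form). The CE term is the per-element
binary cross-entropy averaged over all voxels and channels, with predictions
clipped to $[\epsilon, 1-\epsilon]$, $\epsilon = 10^{-7}$, so every loss is
finite for any input. $\omega$ defaults to 1 (equal weighting — the method's
loss ablation uses an unweighted Dice + CE sum and never prints another
value).

Three derived objectives:

* `global_loss` — the compound loss over the whole volume (stage 1);
* `msf_loss` — both target and prediction are masked by $Md$ at every
  supervision level before the same compound loss; empty masks give exactly
  0, full masks reproduce the global loss;
* `stage_loss(2, ...)` — $L_{Global} + \lambda L_{MSF}$, with $\lambda = 1$
  by default (the ablation optimum among 0.5, 1, 10, 100).

Coarser-level targets are nearest-neighbour downsamplings of the one-hot
ground truth, and coarser-level $Md$ masks are OR-poolings (max over each
$2^3$ block) of the full-resolution mask, preserving "any error here"
semantics. The masks are constants with respect to the gradient: argmax-based
region extraction is not differentiable, so no gradient flows through mask
construction.

An open representational question is whether the masked Dice denominator
should be renormalised by region size; it is not — masked stacks are zero
outside $Md$, so the denominator automatically counts only in-region mass.

## The network

`build_network` constructs an encoder–decoder 3D CNN: stages of
`conv_per_block` 3×3×3 convolutions (instance norm + leaky ReLU, slope
0.01), stride-2 convolutions for downsampling, nearest-neighbour ×2
upsampling with skip concatenation, and 1×1×1 convolution + **sigmoid**
heads on the `dn` highest-resolution decoder stages (each head emits an
N-channel score stack in $[0,1]$; decoding is per-voxel argmax with ties to
the lowest label). Encoder width at round $r$ is
$\texttt{base\_filters} \cdot 2^{\min(r,\, \texttt{filter\_doubling\_rounds})}$,
capped at `filter_cap`.

Three presets:

* `desk` — `base_filters` 4, 3 downsampling rounds, `dn = 3`, symmetric
  decoder. This is the size used by the package's tests and experiments
  (24³ phantoms on one CPU core). Two sizing choices matter and were made on
  stage-1 behaviour alone: (i) width 4 with a *symmetric* decoder — an
  asymmetric (halved) decoder at this width leaves a 2-channel
  full-resolution feature map that demonstrably cannot decode 4 classes
  (two classes never activate); (ii) the desk training preset raises the
  Adam learning rate to 3e-3, because at 600 optimisation steps per stage
  the full-scale rate of 3e-4 leaves stage 1 far from a plateau, and the
  refinement stage presupposes a converged coarse stage ("train until the
  metrics stop improving").
* `baseline` — standard U-Net-family widths: base 32, 5 rounds, widths
  doubling for the first 3 rounds, cap 320, symmetric decoder.
* `paper_scale` — the deepened/widened variant: doubling continues for 4
  rounds, cap 512, asymmetric decoder (decoder blocks at half their encoder
  mirror's width). It has strictly more parameters than `baseline` (~40M vs
  ~23.5M), realising the "deeper network, more encoder filters" design as a
  preset. The exact widths of the original are unpublished; these are
  conventions of the model family, not reproduced facts.

All layers are implemented in the package (im2col + BLAS GEMM convolutions
with hand-written backward passes, verified against central finite
differences to ~1e-7 relative error in the test suite); training is
single-threaded and bit-reproducible for a fixed seed.

## Two-stage training

Stage 1 minimises the global loss. Stage 2 continues training on
$L_{Global} + \lambda L_{MSF}$: for every sample in every batch (default
`mask_refresh = "per_batch"`), the current forward pass is argmax-decoded,
mis-seg regions are extracted with the configured dilation, pooled down the
supervision pyramid, and the masked term is added. `"per_epoch"` instead
caches masks at each epoch start — the looser, literal reading of
"recompute at the end of each epoch"; per-batch is the default because masks
should reflect the network that is being corrected.

The optimizer is Adam (default moments) at `lr_init` = 3e-4 (full scale),
250 batches of 2 per epoch, 300 epochs per stage; the desk preset is 10
batches of 2 for 30 epochs per stage. The learning-rate rule follows the
exponential-moving-average criterion: with EMA coefficient 0.9 (smoothing of
the previous value), if the best EMA training loss within the last 30 epochs
fails to undercut the best earlier value by at least 5e-3, the learning rate
is divided by 5; after a decay the rule is quiet for one full window, so one
plateau cannot trigger cascaded decays. The EMA coefficient and the
cool-down are this package's choices (unpublished in the source method); the
window (30), threshold (5e-3), factor (5) and initial rate are the method's
stated values.

Stage 2 restarts the schedule at `lr_init` by default
(`lr_reset_stage2 = FALSE` continues from the decayed value); the optimizer
moments carry over. Five stage schedules are exposed (`msf_train`,
`run_experiment`): `global_only`, `global_global`, `global_msf`,
`total_total`, and the recommended `global_then_total`.
`compare_schedules()` runs the matched two-arm comparison — one stage-1
trajectory, then `global+λ·MSF` vs `global` control from identical weights,
optimizer state and batch sequences — which isolates the contribution of the
masked term.

## Evaluation

`dice_coefficient` is $2|A \cap B| / (|A| + |B|)$, defined as 1 for two
empty masks. `hd95` extracts boundary voxels (mask voxels with a
face-adjacent outside neighbour), computes both directed
nearest-neighbour distance sets in physical units, takes the 95th percentile
of each (linear interpolation between order statistics) and returns their
maximum; a pooled-percentile variant is a switch. Empty masks yield `NA`
("undefined") rather than an error, so batch evaluations never abort.
Per-epoch monitoring logs mean Dice and the raw disagreement count on a
fixed subset chosen at training start; HD95 appears only in final reports
(it is the expensive metric and adds nothing to convergence tracking).
Units: mm when spacing is available (e.g. from a NIfTI header), voxels
otherwise.

## The phantom generator

`generate_phantom` builds what the method needs to be exercised, without any
clinical data: nested ellipsoidal shells (background, CSF-like, GM-like,
WM-like core by default) whose boundary radii are perturbed by a smooth
random field (`boundary_jitter`, default 1.5 voxels), optional small
ellipsoidal inserts inside the core (each under 2% of voxels — the
hippocampus-scale regime), and an image drawn per voxel from its label's
Gaussian (default means 0, 0.3, 0.55, 0.8 with σ = 0.12, putting adjacent
classes ~1σ apart so boundary voxels are genuinely ambiguous), plus optional
smooth multiplicative bias field and additive noise. Ground truth stays
clean: ambiguity lives in the image, as in the clinical setting of clean
expert labels over hard images. Everything is reproducible from a single
integer seed, and `generate_dataset` writes NIfTI pairs with a 4:1
train:test manifest.

What the phantoms do **not** emulate: MRI physics (no k-space artefacts,
partial-volume mixing or modality-specific contrast), anatomical shape
variability beyond smooth radial jitter, and class geometries more complex
than nested shells. A passing phantom experiment therefore demonstrates the
machinery — region extraction, masked losses, schedules — and the
*direction* of the two-stage effect under controlled ambiguity; it does not
certify clinical-grade accuracy on real MRI.

## Numerical choices and degenerate inputs

* $\epsilon = 10^{-7}$ in the Dice denominator and CE clipping; every loss
  is finite for arbitrary inputs in $[0,1]$.
* Two identically-zero stacks have Dice loss 0 (not $-1$); two empty masks
  have Dice coefficient 1; HD95 of an empty mask is `NA`.
* Argmax ties break toward the lowest label index, deterministically.
* `extract_misseg` with factor 0 on inputs differing at $k$ voxels yields a
  merged mask of exactly $k$ voxels (each differing voxel lies in exactly
  two $M_n$; the OR-merge counts it once).
* Input volumes must be divisible by $2^{n_{down}}$; the forward pass
  rejects others with padding advice rather than silently cropping.
* Stage-2 loss minus stage-1 loss on identical inputs is exactly
  $\lambda L_{MSF} \ge 0$ whenever the masked Dice term does not dominate
  negatively; the invariant asserted in tests is exact additivity.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic data:
oracle comparisons on 6³–10³ grids (hundreds of seeded trials), gradient
checks on 16³ volumes, and the two-stage experiment on 25 phantoms of 24³
(20 train / 5 test), 30 + 30 epochs, medians over 5 seeds with matched
arms. These sizes are the package's desk-scale defaults; the full-scale
presets (`paper_scale` network, 300 + 300 epochs, 250 batches) are provided
for users with the hardware and data to run them.

## Known limitations

* The desk-scale experiment shows the qualitative two-stage effect; absolute
  Dice values at 24³/600 steps are far below what a full-scale nnU-Net-class
  training achieves and are not comparable to published benchmark tables.
* No data augmentation, cross-validation driver, patch-based inference,
  or post-processing (largest-component filtering) — all deliberately out of
  scope.
* Instance-norm makes conv biases redundant (their gradient is exactly zero
  under normalisation); they are retained for the `norm = "none"` variant.
* The mis-seg mask is recomputed from scratch (no incremental update); at
  paper scale with `per_batch` refresh this doubles region-extraction work
  relative to `per_epoch`.
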