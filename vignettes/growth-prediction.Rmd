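---
title: "Multi-task prediction of pulmonary nodule growth: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task prediction of pulmonary nodule growth: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nogrownet)
```

## The problem

Radiologists assess indeterminate pulmonary nodules by comparing CT scans
taken months apart: has the nodule grown, and has its internal density
changed? `nogrownet` models this longitudinal process directly. Given a
single baseline volume of interest (VOI) centred on a nodule and a requested
follow-up horizon, it synthesizes the predicted follow-up appearance and the
predicted nodule mask. Growth is decomposed into two physically distinct
components that are learned jointly:

* a **deformation** component — a dense displacement field $u$ defining the
  warp $\phi = \mathrm{id} + u$, which captures volume and shape change;
* a **texture** component — an additive intensity residual $x_{res}$ inside
  the nodule, which captures density evolution.

The fused prediction is
$$\hat{y} = x_{warp} + x_{res} \times s_{warp},$$
where $x_{warp} = \phi \circ x$ is the warped baseline image and
$s_{warp} = \phi \circ s$ the warped baseline mask. The residual only acts
inside the (soft) warped mask, so the background is carried over by the warp
alone. A third, segmentation decoder predicts the follow-up nodule mask
directly; at inference time it can also supply the baseline mask, so manual
annotation is not required.

## Architecture

The network is a compact 3D encoder–decoder. The shared encoder uses
stride-2 convolutions with LeakyReLU (negative slope 0.2) over two
resolution levels plus a bottleneck. Each of the three task decoders
(deformation, texture, segmentation) upsamples with transposed convolutions
(kernel 2, stride 2) and has its own extra convolutions on the skip
connections, giving tasks room to specialize features the encoder shares.
Channel widths double per level from `base_channels` (16 by default, 8 in
the small preset).

Temporal conditioning enters at the bottleneck. The follow-up interval in
days is truncated at 600 and binned into 30-day months,
$t_{itv} = \lfloor \min(\Delta t, 600)/30 \rfloor \in [0, 20]$, then encoded
with fixed sinusoids of geometrically increasing wavelength
($\sin(t/100^{2i/d_{fm}})$, $\cos(t/100^{2i/d_{fm}})$) and
broadcast-concatenated onto the bottleneck feature map. We use the floor in
the binning (the bracket could also be read as rounding) and admit
$t_{itv}=0$, which the regularization losses below rely on, even though the
clinical prediction range starts at 1 month. The embedding length $d_{fm}$
defaults to the bottleneck channel count. Where exact architectural details
are not fixed by the problem (channel counts per level, number of skip
convolutions, the injection point of the time code), we chose the smallest
configuration that trains stably on CPU and exposed it in
`network_config()`.

Two initialization choices matter. The displacement head is
zero-initialized, so an untrained network computes the identity warp — this
stabilizes the correlation loss early in training and is asserted by a unit
test. The texture head is a tanh scaled to $[-2, 2]$ so the residual can
traverse the full normalized intensity range.

With deep supervision enabled, an auxiliary *direct* prediction is emitted
from the half-resolution stage of the texture decoder:
$\hat{y}_{ds} = x_{warp}\times(1-s_{warp}) + x_{texture}\times s_{warp}$.
The direct form forces the texture decoder to extract complete nodule
appearance from the encoder, while the residual form of the final output
keeps fitting easy; the two fusions agree exactly when
$x_{texture} = x_{warp} + x_{res}$ on the mask support.

The segmentation decoder is supervised with the *follow-up* mask: the warped
baseline mask $s_{warp}$ gates the texture fusion, while the segmentation
output is the mask actually reported, which keeps recall-oriented slack in
the deformation branch from contaminating the final volumetry.

## Losses

Deformation task (weights $\lambda_1 = 0.5$, $\lambda_2 = 10$,
$\lambda_3 = 1$):

* **Similarity**: $1 - \mathrm{NCC}(y, x_{warp})$, where NCC is the mean
  over voxels of the squared local Pearson correlation in a $9^3$ window.
  The squared form is what keeps the value in $[0, 1]$; the window size is a
  convention we fixed at the value standard in displacement-field
  registration. Border windows use the in-volume voxel count, and an
  $\varepsilon = 10^{-5}$ in the denominator defines locally constant
  windows as contributing zero.
* **Mask overlap**: Tversky loss $1 - TI$ with $\alpha = 0.2$,
  $\beta = 0.8$, computed on soft (interpolated) masks. The printed index is
  a similarity, so the loss is its complement. $\beta > \alpha$ penalises
  false negatives harder — under-covering the grown nodule is worse than
  over-covering it, because the texture branch can only paint inside
  $s_{warp}$. A small $\varepsilon = 10^{-7}$ in numerator and denominator
  makes two empty masks count as perfect agreement.
* **Smoothness**: mean squared forward differences of $u$, with each of the
  nine component/axis partials averaged over its valid positions so a linear
  ramp of slope $s$ scores exactly $s^2$ and the weight is
  resolution-independent.
* **Baseline consistency**: $1 - \mathrm{NCC}(x, \phi_0 \circ x)$ from a
  second forward pass conditioned on $t_{itv} = 0$ — no elapsed time should
  mean no change.

Texture task ($\lambda_1' = 1$): an L1 similarity between $\hat{y}$ and the
true follow-up (a mean-square variant is selectable via the ablation flag;
the similarity symbol in the texture total is ambiguous between the two, and
L1 is the default), plus the zero-interval regularizer
$\mathrm{mean}(x_{res,0}^2)$. With deep supervision the auxiliary
$\hat{y}_{ds}$ receives the same similarity loss. The segmentation task uses
soft Dice loss.

All losses are means over voxels, so the stated weights do not depend on the
VOI size. Displacements are in voxel units (1 voxel = 1 mm after
preprocessing); out-of-domain warp samples are border-clamped rather than
zero-filled so no artificial air is dragged into a nodule-centred VOI;
interpolation is trilinear everywhere during training (masks must stay
differentiable for the Tversky loss) and masks are thresholded at 0.5 only
for evaluation and export.

## Training schedule

AdamW ($\beta_1 = 0.9$, $\beta_2 = 0.999$, weight decay 0.01 — optimizer
internals not otherwise pinned down) with learning rate 0.001 for the
deformation and segmentation paths and 0.0005 for the texture path. Stage 1
trains everything jointly on the unweighted sum of the three task losses
(intra-task weights are specified above; no inter-task weighting is
prescribed, so we use the plain sum). Stage 2 freezes the shared encoder —
the training routine records the maximum absolute encoder weight drift,
which must be exactly zero — and fine-tunes each decoder separately. We
interpret "separately" as sequential per-decoder fine-tuning on one model in
the fixed order warp → texture → segmentation; independent per-task copies
would triple the memory without a clear benefit at this scale. The reference
schedule is 200 epochs for stage 1 and 200 per task in stage 2 (the
`"full"` preset); the `"small"` preset used throughout the tests runs 5 and
1–2 per task, which is enough for the phantom cohort below.

Every optimization step evaluates the extra $t_{itv}=0$ decoder passes
feeding the two regularizers. The encoder is time-independent, so both
passes share one encoding; this is an exact refactoring, not an
approximation. Training is single-threaded and fully deterministic given
the seed: two runs with the same configuration produce bit-identical
weights.

## The synthetic phantom cohort

The real cohort this model family targets (hundreds of patients with paired
baseline/follow-up scans at 0.5–1.5 mm slice thickness, nodules 3–30 mm,
intervals of 8–1392 days averaging about a year) is not publicly available,
so the package ships a generator whose *structure* mirrors it: isotropic
VOIs with a centred nodule, paired timepoints, a fraction of subjects with
two follow-ups yielding the chronological pair sets {T0&T1, T0&T2, T1&T2},
and patient-level fold splitting.

Each phantom nodule is an ellipsoid with a fixed degree-2
spherical-harmonic radial perturbation (amplitude up to 0.3 of the radius),
so shapes are irregular but growth is shape-preserving: the follow-up
simply scales the radius field by $2^{t/(3\,\mathrm{VDT})}$, realizing the
standard clinical model of exponential volume growth with a
volume-doubling-time (VDT) parameter. VDTs are drawn from 60–720 days
(90–365 in the growth-recovery experiment, the range typical of
solid malignant nodules); intervals from a gamma distribution with mean 376
days truncated to [8, 1392]; interior density starts in $(-0.2, 0.6)$ on
the normalized scale and drifts linearly with time (0–0.08 per 100 days),
so the texture branch has signal beyond pure deformation. The background is
smoothed Gaussian noise around a parenchyma level of $-0.75$ with up to
three bright tube distractors standing in for vessels. A one-voxel
smoothstep at the analytic surface supplies partial-volume edges. The
background scene is frozen per nodule, which makes a zero-day interval
reproduce the baseline exactly — convenient for testing, though real
repeat scans would differ in noise.

What passing tests on phantoms do *not* show: performance on real lung
anatomy. The generator has no pleural attachments, fibrosis, vascular
convergence or non-exponential growth, and its intensity statistics are far
simpler than CT texture. Results on this cohort validate the machinery
(losses, conditioning, optimization, evaluation), not clinical accuracy.

## Evaluation

PSNR, SSIM and DSC, each also restricted to the nodule region (the voxels
of the ground-truth follow-up mask — the natural reading of "nodule
region"). Images live in $[-1, 1]$, so the dynamic range constant is
$L = 2$ for both PSNR and the SSIM stabilizers $c_1 = (0.01L)^2$,
$c_2 = (0.03L)^2$; absolute dB values from other implementations may
use other range conventions and are not directly comparable. SSIM uses a
uniform $7^3$ window with population statistics, the simplified unit-
exponent form with $c_3 = c_2/2$. PSNR of identical images is capped at
100 dB for serializability; two empty masks score DSC 1.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run the small preset: $24^3$ VOIs,
8 base channels, a 40-pair smoke run (5 + 2-per-task epochs), and a
growth-recovery experiment training on 200 pairs (5 + 1-per-task epochs)
with 40 held-out pairs from disjoint patients. These sizes were chosen so a
complete from-scratch run takes minutes on one CPU core while leaving the
growth signal recoverable: on the held-out phantoms the predicted follow-up
mask volume correlates with the truth at $r \ge 0.8$, mean DSC exceeds
0.70, and the predicted volume is non-decreasing across 1→18-month horizons
for at least 80% of growing nodules (a 1% voxel-count tolerance absorbs
threshold flicker at the mask boundary). The ablation check compares the
full configuration (deep supervision + Tversky + L1) against the base
configuration (mean-square, Dice, no deep supervision) on five seeds of a
miniature $16^3$ cohort.

## Known limitations

* The autodiff engine implements exactly the ops this architecture needs;
  it is not a general-purpose framework.
* Batch statistics (no normalization layers) — at these model sizes
  normalization was unnecessary, but large presets may train slower without
  it.
* The cascade ablation row approximates a two-network cascade by sequential
  single-task training of one shared-weight model; it is a comparator, not
  a faithful re-implementation of external baselines.
* Phantom realism as discussed above; in particular the density drift is
  spatially uniform inside the nodule up to a small fixed texture field.
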