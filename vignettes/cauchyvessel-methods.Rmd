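---
title: "Retinal vessel segmentation with a Cauchy matched-filter feature map and a U-Net"
author: "cauchyvessel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal vessel segmentation with a Cauchy matched-filter feature map and a U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Blood vessels in colour fundus photographs are dark, curvilinear structures
on a reddish, unevenly illuminated background. Because the retinal tissue
itself is perfused, the red channel carries little vessel contrast and a
disproportionate share of the sensor noise; thin vessels (1--3 px at DRIVE
resolution) are close to invisible. Classical matched filtering and modern
convolutional segmentation attack this problem from opposite ends:
a matched filter encodes an explicit physical model of a vessel's
cross-section, while a U-Net learns whatever discriminates vessel pixels
from background in the training data. This package combines them: the
maximum response of an oriented Cauchy matched-filter bank *replaces the
red channel*, and the network trains on the resulting three-plane
"Cauchy-G-B" feature map.

## The matched filter

The intensity dip across a vessel is modelled by the Cauchy probability
density

$$C(x) = \frac{1}{\pi\gamma\left[1 + \left(\frac{x - x_0}{\gamma}\right)^2\right]},$$

a heavier-tailed curve than the traditional Gaussian template, which fits
the slow shoulder of real vessel profiles better. The base kernel samples
$-C(x)$ (negated: vessels are *dark*, so the correlation response to a
vessel should be positive) at the `T = 9` integer offsets
$x \in \{-4, \dots, 4\}$ across the vessel, replicated over `L = 8` rows
along the vessel axis, with `gamma = 1` px and `x0 = 0`. The kernel is
mean-subtracted so that constant background contributes exactly nothing.

Twelve copies rotated by $k\pi/12$, $k = 0, \dots, 11$, cover all
orientations (the profile is symmetric along the vessel axis, so
$[0, \pi)$ suffices). Rotation uses inverse-mapped bilinear interpolation
on a fixed odd square support (side 13, the smallest odd integer at least
$\sqrt{T^2 + L^2}$), and each rotated kernel is re-centred to zero mean
because interpolation breaks exact mean-freeness. Filtering is
*correlation* (not flipped convolution) with reflect padding; the
per-pixel maximum over the twelve kernels is the response map.

Numerical notes:

* Correlation is computed by FFT on a reflect-padded raster; against a
  literal per-pixel, per-tap loop it agrees to well below $10^{-8}$ on
  unit-range images, which the test suite asserts.
* `rescale_unit` maps a raster affinely onto $[0, 1]$; a constant raster
  maps to all zeros rather than an arbitrary constant, so degenerate
  inputs stay degenerate instead of being invented into contrast.

## Preprocessing order

The pipeline is CLAHE → per-channel standardization → matched filter on
the green channel → unit rescaling → assembly as (response, green, blue).
The description of the preprocessing stage genuinely underdetermines
whether contrast enhancement precedes standardization; this order was
fixed because CLAHE is defined on integer-binned histograms (so it should
see the raw 8-bit data) while the network wants bounded, comparable
inputs (so rescaling comes last). The matched filter runs on the *green*
channel — the highest-contrast channel for vessels and the standard
choice in the matched-filter literature; the raw red channel is discarded
entirely.

Standardization uses the population standard deviation and, when a
field-of-view (FOV) mask is available, computes its statistics over FOV
pixels only — otherwise the black surround, roughly a quarter of a
DRIVE frame, dominates the mean. All three output planes are zeroed
outside the FOV so the network cannot learn the FOV rim as a feature.
CLAHE defaults (clip limit 2, 8×8 tiles) are exposed in the
configuration; the raster is reflect-padded to tile multiples because the
underlying implementation requires divisibility.

## Patches, the network, and training

Training samples 500 overlapped 64×64 patches per image, centres uniform
over FOV pixels at least half a patch from the border (so patches never
need padding), labels cut from the manual segmentation at the same
coordinates. Flip augmentation (identity, horizontal, vertical, both)
quadruples the set — with 20 DRIVE-scale training images this is the
40,000-patch pool — and a patch-level 90/10 split yields train and
validation sets. Test images are tiled *without* overlap (reflect-padded
on the bottom/right edges) and predictions are stitched back; the
round trip is exact, which the suite asserts on random shapes including
the 768×584 frame that produces 120 tiles.

The network is a standard U-Net: four encoder steps of two 3×3
same-padding convolutions and a 2×2 max pool, filters doubling from 32;
a two-convolution bottleneck; four decoder steps of 2× nearest-neighbour
upsampling, skip concatenation, and two convolutions; ReLU everywhere and
a 1×1 two-class SoftMax head whose vessel plane is the output. Filter
doubling, 3×3 kernels, concatenation skips and nearest upsampling are
fixed as the conventional choices where the architecture description is
silent; batch normalization is deliberately absent. The 64×64×1
floating-point output is reconciled with the K-class SoftMax by emitting
the vessel-class plane of a two-channel head, whose per-pixel
probabilities sum to one. Hidden layers use He initialization; the head
is zero-initialized so every run starts from the uniform 0.5/0.5
prediction — a random initial class bias can destabilize narrow networks
in their first epochs, freezing them at the class-prior prediction.

Training minimizes binary cross-entropy (the natural loss for a
two-class SoftMax against binary labels) with Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$ — the printed pairing lists both as
$\beta_2$, read as the standard values), initial learning rate
$\eta = 0.01$, 200 epochs by default, batch size 32. The learning rate
shrinks by ×0.9 at each 10-epoch boundary *when the loss has saturated*;
"saturated" is operationalized as the best validation loss improving by
less than `plateauTol` (default $10^{-4}$) over the last 10 epochs, and
`plateauTol = Inf` recovers the unconditional every-10-epochs reading of
the schedule. The best-validation-loss weights are restored after
training. The implementation is a from-scratch float32 im2col/BLAS
network; with a fixed seed, initialization, shuffling, forward and
backward passes are bit-reproducible on a given platform.

## Evaluation

Vessel is the positive class. Confusion counts are restricted to the FOV
(counting the black surround as true negatives would inflate accuracy and
specificity for free). Accuracy, sensitivity, specificity and precision
follow the four standard ratios; a 0/0 ratio is reported as `NA`, never
silently coerced. The ROC sweep binarizes at $p \ge \tau$ over
$\tau \in \{0.01, \dots, 0.99\}$, computes TPR against the standard
false-positive rate FP/(FP+TN), and appends (0,0) and (1,1) before
trapezoidal integration. (A printed variant of the FPR formula involving
FN in the denominator is inconsistent with the accompanying specificity
definition and is not reproduced.) The threshold-sensitivity table
reports all four metrics per $\tau$; the flatness of this table around
$\tau = 0.5$ is what justifies the default operating point.

## The phantom generator

Real fundus data cannot ship with a package, so every stage is exercised
on synthetic phantoms with known ground truth. A phantom is a circular
FOV inscribed in a DRIVE-scale frame (584×565) on a black surround; the
background is red-dominant (RGB means 0.72/0.42/0.22) with a radial
illumination falloff and a low-frequency shading field. Each of 6 vessel
trees grows inward from a boundary seed as a branching random walk
(direction jitter sd 0.07 rad/step, branch probability 0.012/step, child
width ×0.72, width decay 0.997/step — bookkeeping constants, with no
claim of biological realism). A centreline point of width $w$ subtracts
`depth`×$C(d)/C(0)$ from the image, where $d$ is the distance to the
centreline and $\gamma = w/2$, so the half-peak contour of the profile
lies exactly at the nominal vessel edge; the ground-truth mask is that
half-peak contour — the visible core a human annotator would trace.

The dip is strongest in green (×1.0 vs ×0.35 red, ×0.55 blue) and the
red channel receives twice the Gaussian noise of the others, emulating
the noisy-red premise that motivates replacing that channel. Defaults
are vessel widths 1--7 px, dips 0.15--0.35 in intensity units, noise
sd 0.06: a *hard* regime chosen away from the clean-image ceiling, where
denoising by the matched-filter prior can actually matter — on nearly
noise-free phantoms every method saturates near-perfect AUROC and
comparisons are uninformative. Intensities are snapped to the 8-bit grid
at generation time so written TIFFs read back bit-exactly. Under the
default spec the vessel mask covers roughly 4--8% of the FOV.

What phantoms do *not* model: pathology (lesions, exudates), the optic
disc, vessel texture and central reflex, JPEG artefacts, inter-annotator
ambiguity. Passing the phantom suite therefore demonstrates that the
pipeline is implemented correctly and can learn vessel structure from
realistic geometry and noise — not that it reaches any particular
accuracy on clinical data.

## The scaled-down study

`phantomStudy()` runs the entire pipeline at reduced size: 12 phantoms
(10 train / 2 held out), 50 base patches per training image (2,000 after
augmentation), 32×32 patches, a depth-4 U-Net with 4 base filters,
30 epochs — sizes chosen so the study completes in minutes on one CPU
while still exercising every stage at full fidelity. One training
parameter is width-matched rather than inherited from the reference
configuration: the study's initial learning rate is 0.003, because at
the reference η = 0.01 a 4-filter network is prone to rectifier die-off
— Adam's per-parameter steps are initially of order η, and with so few
units per layer a single aggressive epoch can silence entire layers,
freezing the network at the class-prior prediction. The full-width
reference model keeps η = 0.01. The raw-RGB
ablation re-runs the identical experiment (same patch coordinates, same
initialization seed) with the preprocessed red channel kept in plane 1
instead of the matched-filter response; comparing held-out AUROC between
the two arms isolates the contribution of the response channel. The
32-pixel patch and 4-filter width were fixed once for runtime, not tuned
to any outcome; the paired-seed design means the comparison between arms
is unaffected by these choices.

## Known limitations

* The U-Net trains on a single CPU core; at the full reference size
  (base 32 filters, 64×64 patches, 40k patches, 200 epochs) training is
  a multi-hour to multi-day job and is deliberately not part of any
  automated run.
* GIF masks (DRIVE's native mask format) are not readable in this
  toolchain; masks are written and read as PNG instead.
* Probability maps persist as 32-bit float TIFF rather than 16-bit PNG;
  this is lossless for ROC reproduction.
* The phantom generator's branching rule is a convenience, not vascular
  biology; morphometric conclusions should not be drawn from phantoms.
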