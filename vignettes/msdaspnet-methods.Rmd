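---
title: "Dual-attention spatial-pyramid lesion segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-attention spatial-pyramid lesion segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multiple sclerosis (MS) lesions appear on FLAIR MRI as small, irregular,
hyperintense foci in white matter. Segmenting them is hard for exactly the
reasons that make them clinically important: they are tiny relative to the
image (foreground often well below 1% of pixels), low-contrast, and
heterogeneous in shape and location. `msdaspnet` implements a U-shaped
convolutional network for this task together with everything needed to
exercise it end to end on a single CPU: a synthetic FLAIR-like phantom
generator with exact ground truth, the full 2D preprocessing chain,
geometric co-augmentation, binary cross-entropy training with
patient-disjoint splits, a six-metric evaluation panel, and Grad-CAM
attention maps.

## The network

The architecture is an encoder–decoder with three additions over a plain
U-Net, all implemented (forward and backward) in this package with
RcppArmadillo; there is no external deep-learning runtime.

**Encoder.** Five convolutional blocks in the VGG-16 topology: 13
convolutional layers in blocks of (2, 2, 3, 3, 3), each layer a 3×3
cross-correlation with "same" zero padding followed by ReLU
(`F_l = relu(W_l * F_{l-1} + b_l)`), each block followed by 2×2 max
pooling. The reference profile uses the VGG-16 widths
(64, 128, 256, 512, 512); grayscale inputs are replicated to three
channels so the stem matches the VGG shape and pretrained encoder weights
can be dropped in (from an RDS file; random He-normal initialisation is
the default and is what all tests use). Skip features `E1..E4` are the
last pre-pool activation of blocks 1–4 (strides 1, 2, 4, 8); the
bottleneck input is the block-5 *post-pool* output at stride 32, so valid
input sizes are multiples of 32.

**ASPP bottleneck.** Parallel branches over the same bottleneck map: a
1×1 convolution (rate 1), three 3×3 atrous convolutions at dilation rates
6, 12, 18, and a global-average-pooling branch (spatial mean → 1×1
convolution → broadcast). The branch outputs are concatenated channel-wise
and fused by a 1×1 convolution with ReLU. Two published equations describe
this stage differently — one as a *sum* of branch responses, one as
*concatenation + 1×1 fusion*; the accompanying prose confirms
concatenation, which is what we implement.

**Dual-headed attention (DHA) on skips.** A sequential spatial-then-channel
gate. Spatial: per-pixel channel mean and channel max, concatenated to a
2-channel map, a 7×7 convolution, sigmoid → map `A_s ∈ (0,1)^{H×W}`,
applied multiplicatively. Channel: per-channel spatial mean and max
(length 2C), a two-layer dense net `sigmoid(W2 · relu(W1 z) + b2)`
(no first-layer bias, following the published equation) → vector
`A_c ∈ (0,1)^C`, applied per channel. The equation chain feeds the spatial
output into the channel descriptors, so that order is normative, even
though the pseudocode description lists channel first. The pseudocode also
attends the *upsampled decoder* feature where the equations attend the
*skip* feature; we default to the skip side (`attention_site = "skip"`)
and expose `"upsampled"` as a configuration alternative. With all gate
sigmoids saturated at 1 the block is the identity and the network reduces
to a plain skip-connected encoder–decoder — a property the test suite
asserts.

**Decoder.** Because the bottleneck sits at stride 32 and the shallowest
skip at stride 1, the decoder has five upsampling stages: one stem stage
without a skip, then four levels that upsample ×2 (bilinear, followed by a
3×3 convolution — chosen over transposed convolution to avoid checkerboard
artifacts), concatenate the DHA-gated skip feature, and apply two 3×3
convolutions with ReLU and dropout. The five published decoder widths
(16, 32, 64, 128, 256) map one per stage, deepest to shallowest; this
also resolves the apparent conflict between "encoder initialised with
VGG-16" and the 16–256 filter list, which cannot both describe the
encoder. A 1×1 convolution and a sigmoid produce the per-pixel lesion
probability; masks are thresholded at 0.5 by default.

## Training

Binary cross-entropy, `-Σ_i [y_i log o_i + (1-y_i) log(1-o_i)]`, with
probabilities clamped to `[1e-7, 1-1e-7]`. The raw sum scales with the
image area, so the optimised quantity is the per-pixel mean; both are
reported. Optimisation is Adam (learning rate 0.001), batch size 4,
dropout 0.2 (after the ASPP fusion and after each decoder conv pair —
the published recipe states the rate but not the placement), 100 epochs
in the reference configuration. Splits are computed at the *patient*
level with a seeded shuffle (`ceiling(n · fraction)` test patients;
default fraction 0.10, with 0.15 and 0.20 used in ablations), and a
leakage guard aborts training if any test patient appears in the
training manifest. The encoder-freezing option follows the description
of transfer learning with a pretrained encoder — frozen "during the
initial training", with no unfreezing schedule given — so
`freeze_epochs` defaults to the whole run; for a randomly initialised
encoder freezing is pointless and the CPU-scale runs set it to 0. There
is no validation split, learning-rate schedule, or early stopping, since
none are part of the recipe.

## Preprocessing

Volumes are reoriented so axis 1 points inferior→superior and decomposed
into axial slices. Slice selection applies, in order: a central band
keeping `central_band_fraction` (default 0.70, from a published 65–70%
range) of the axial extent, then a minimum-lesion-size rule keeping slices
with ≥ 5 foreground mask pixels. "Lesion size" is read as total foreground
pixels in the slice, the simplest reading; a per-connected-component mode
is available behind a flag. Each slice pair carries its source-volume
depth so the band is well-defined on filtered subsets and the selection is
idempotent.

Per retained slice: skull stripping (contrast stretch to [0,1], histogram
equalization, Otsu threshold, morphological opening then closing with a
disk, largest connected component, hole filling — the image is masked, the
lesion mask never is), non-local-means denoising (patch 3, window 11,
`h = 0.8 ×` a robust noise-sigma estimate — parameters are not published),
bias-field correction, per-slice min–max normalization to [0, 1], and
bilinear resizing to the target (256×256 reference; masks are resized by
nearest neighbour and re-binarized). Bias correction defaults to a
least-squares degree-2 polynomial fit to log-intensity over the brain
region, divided out after renormalization to unit mean; N4 itself is prior
published work the pipeline *calls*, not defines, so it is exposed as a
delegated hook (`bias_correction = "delegated_n4"` with a user-supplied
function) rather than re-implemented. The web-platform brain extraction
used in the original pipeline is replaced by the Otsu/morphology sequence
above, which is the algorithmic description available.

## Augmentation

Three co-transforms, applied identically to image (bilinear) and mask
(nearest neighbour, re-binarized): rotations at 45°, 90°, 125° about the
image centre; centre zooms at 1.5× and 2× (the output keeps its shape, so
zooming in implies a centre crop — how scaled images are refit is not
published); and one horizontal translation (default 10% of width, also
unpublished). The expansion factor is one output per listed parameter:
1 original + 3 rotations + 2 scalings + 1 translation = 7× — the
operations are published, the count is this package's choice and is
configurable. Augmentation applies to training slices only. Nearest-mask
and thresholded-bilinear-image supports can legitimately differ on the
one-pixel band where the interpolated value sits at exactly ~0.5, so the
co-transform tests assert support equality away from that ambiguity band
and exactly for grid-exact transforms (90° rotations, integer shifts).

## The phantom generator

The phantom emulates the gross intensity structure the preprocessing and
network rely on: dark background (0), an ellipsoidal "brain" at a fixed
reference level (100), an optional brighter elliptical skull shell (180)
separated from the brain by a dark gap, spherical hyperintense lesions at
`100 × lesion_contrast` (contrast > 1 so lesions are FLAIR-like bright),
a smooth multiplicative bias field (1 + amplitude × a random degree-2
polynomial, zero-mean and unit-max over the brain — exactly the artifact
the polynomial correction removes), and additive Gaussian noise. Fixed
reference levels make oracle checks exact: with no bias and no noise, the
lesion mask is *identically* the set of supra-tissue-level brain pixels.
Lesions are placed by rejection sampling (≤ 1000 attempts each,
conservative inside-ellipsoid test, > 1-voxel mutual separation) so
26-connected labelling recovers the lesion count exactly. All randomness
derives from the single spec seed, and the caller's RNG state is restored
afterwards. No published lesion-size distribution exists for the real
cohorts, so the defaults (radius 2–4 voxels, contrast 1.5) are simply
plausible for punctate white-matter lesions and are not calibrated to any
dataset.

What the phantom deliberately does **not** model: MRI physics (no k-space,
no Rician noise), anatomy (no ventricles, gyri, or tissue classes),
multi-modal contrasts, or longitudinal change. Passing phantom-based tests
therefore demonstrates that the pipeline and optimiser are *implemented
correctly* — it says nothing about segmentation accuracy on clinical
FLAIR, which requires the restricted-access cohorts and full-scale
training runs outside this package's scope.

## Numerical choices and degenerate inputs

* Convolution is cross-correlation (no kernel flip) with zero padding
  `dilation·(k−1)/2`; the tests pin this convention against brute-force
  enumeration.
* Max pooling pads odd extents with −10³⁰⁰ so no real activation is lost;
  ties take the first window element.
* Bilinear resampling uses half-pixel centre alignment; its backward pass
  is the exact adjoint (asserted via ⟨u, Av⟩ = ⟨Aᵀu, v⟩).
* Channel/spatial max descriptors backpropagate to the arg-max element
  (first index on ties).
* Initialisation is He-normal for ReLU convolutions and Xavier for the
  sigmoid-output attention and head layers; the head *bias* starts at −2
  rather than 0, an imbalance-aware choice (lesion foreground is ≈1% of
  pixels, so starting near the foreground prior keeps early epochs from
  being spent suppressing background and makes convergence much less
  dependent on the initialisation draw).
* BCE clamps probabilities at 1e-7; metric ratios with zero denominators
  return 1 when the requirement is vacuous (empty ground truth met by an
  empty prediction) and FPR returns 0 — degenerate slices never arise from
  the preprocessing (empty-mask slices are filtered), so this convention
  only affects user-supplied data.
* Per-slice metric averaging is the default aggregation; pooled-count
  aggregation is available. The Dice–Jaccard identity
  `J = D/(2−D)` holds per slice, not for averages — published summary
  tables where the identity fails for the printed means indicate averaged
  per-image metrics, which motivated the default.
* Grad-CAM needs a scalar objective; for dense output we use the mean
  pre-sigmoid logit over predicted-foreground pixels (all pixels if the
  prediction is empty). The default target layer is the ASPP fusion
  output; encoder skips are also exposed. Identically zero gradients give
  an all-zero heatmap rather than 0/0.

## Scale profiles

The `"reference"` profile is the published geometry (256×256 inputs,
VGG-16 widths, 100 epochs). Training it is far outside a single-CPU
session, so the package also defines a `"desk"` profile with the same
topology at reduced width (128×128 inputs, encoder widths 8–64,
32-channel ASPP branches) used by the test suite and the acceptance
script: 8 preprocessed phantom slices, ≤ 300 Adam steps, which a single
CPU completes in minutes and which reliably reaches a mean training Dice
above 0.9 — an overfit-capacity check that exercises every layer's
forward and backward pass. A width-halved variant was also tried and
plateaus at an all-background prediction within the step budget, so the
desk widths are the smallest of the profiles examined that demonstrate
learning; they were fixed before the acceptance run and are not tuned
per seed.

## Known limitations

* The full network is only approximately translation-covariant: the GAP
  branch and the channel-attention descriptors are global, and rate-18
  kernels at a 4×4–8×8 bottleneck always overlap the zero padding. The
  suite therefore asserts exact covariance where it genuinely holds —
  encoder features under stride-compatible (32-pixel) shifts with content
  away from borders.
* Pretrained VGG-16 weights are supported as an input format but not
  bundled (they require a download); random initialisation is the tested
  path.
* Published headline Dice scores on the real MS cohorts (0.83–0.87) are
  not reproducible here: the datasets are restricted-access and the
  training budget is ~100 GPU epochs. The package reproduces the
  *arithmetic* of those comparisons and validates the machinery on
  phantoms.
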