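---
title: "Reconstructing vertebral CT volumes from biplanar X-rays: models and methods"
author: "BiplanarCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing vertebral CT volumes from biplanar X-rays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BiplanarCT)
```

# The problem

A CT scan of the spine resolves vertebral anatomy in three dimensions but
costs an order of magnitude more radiation dose than a pair of plain
radiographs. This package implements, end to end, a workbench for studying
whether a conditional generative model can recover a 3D vertebral CT volume
from just two X-ray views — one anterior, one lateral — when the model is
trained on synthetic X-rays rendered from segmented CT volumes. It covers
the complete chain: synthetic vertebral phantoms, mask-driven region-of-interest
cropping, digitally reconstructed radiographs (DRRs), X-ray preprocessing and
paired-sample packaging, a two-view feature-fusion least-squares GAN, a
volumetric evaluation suite, and a biplanar-angle sensitivity sweep.

Because genuine spine CT collections with vertebra masks are access-restricted,
the package is self-sufficient: a procedural phantom generator supplies
CT-like volumes with voxel-exact segmentation masks, so every stage is
testable without external data.

# Conventions

All volumes are stored as arrays ordered (z, y, x) with z running inferior to
superior, y posterior to anterior, and x right to left; voxel sizes are in
millimetres. Intensities live on a Hounsfield-like scale spanning
[0, 2500]; normalized volumes divide by the `intensityScale` (2500 by
default) and clip to [0, 1]. The scale ties the two error families together:
on cubic volumes the whole-volume mean absolute error equals the scale times
its slice-wise normalized counterpart exactly, so a single configurable
number governs both readouts. 2500 spans the range from air to dense
cortical bone on the package's Hounsfield-like scale.

# The phantom generator

`generatePhantom()` builds a column of `nVertebrae` elliptic-cylinder
vertebral bodies, stacked along z and separated by `discGapMm` (default
4 mm). Each body draws its right–left semi-axis from `bodyRadiusMm`
(default 9–13 mm) and its height from `bodyHeightMm` (default 8–12 mm); the
posterior–anterior semi-axis is fixed at 0.75 of the drawn radius so the
anterior and lateral silhouettes genuinely differ — the property the
two-view fusion model must exploit. A posterior arch block (6 mm deep, half
the body width) adds further view asymmetry. Tissue is painted as a ~1.5 mm
cortical shell at 1500, a trabecular interior at 500, and a surround at 50,
with optional clipped Gaussian noise (default sd 20). The companion mask
labels vertebra i with label i, voxel-exactly.

What the phantom does *not* emulate: realistic Hounsfield calibration,
pedicles/processes beyond the single arch block, endplate curvature,
degenerative morphology, or scanner artifacts. Tests passing on phantoms
therefore demonstrate that the pipeline's machinery is correct and that the
model can learn view fusion on asymmetric shapes — not that reconstruction
quality transfers to clinical data. Phantom intensity defaults are
uncalibrated placeholders on the [0, 2500] scale.

Cohorts are reproducible under parallel generation because each case derives
its own RNG stream from the master seed and the case index
(`generateCohort()`).

# ROI cropping

`maskBoundingBox()` returns the tightest inclusive box around all nonzero
labels, and `cropToMask()` restricts CT and mask to it, so the output extent
per axis is `max - min + 1` (both ends inclusive — the half-open convention
is the other common choice, hence the explicit note). The origin shifts by
`(min - 1) * voxelSize`, preserving world coordinates. Cropping uses the
union of all vertebra labels, producing a single volume per case. An
all-zero mask is an error rather than a silent no-op.

# DRR synthesis

`projectDRR()` renders a parallel-beam DRR: the volume is rotated about z by
the view angle (bilinear in-plane resampling; `cospi`/`sinpi` make quarter
turns exact lattice permutations, which the test suite exploits), normalized
intensities $v$ are mapped to opacities $\alpha = \mathrm{tf}(v)$ by a
six-point piecewise-linear opacity transfer function, and each ray along y
composites front to back with the emission–absorption rule

$$C \leftarrow C + (1 - A)\,\alpha_i v_i, \qquad A \leftarrow A + (1 - A)\,\alpha_i,$$

at sample spacing `stepMm` (linear interpolation between slices when the
step is not a whole voxel). The accumulated opacity $A$ is monotone and
bounded by 1 by construction. The image is min–max rescaled to [0, 1] and
resampled to the detector size (128² by default); an all-constant
accumulation (nothing absorbs or emits) degenerates the rescale, and the
convention is an all-zeros image plus a warning rather than an error.

The default transfer function —
(0, 0), (0.10, 0), (0.30, 0.02), (0.55, 0.10), (0.75, 0.35), (1.00, 0.85) —
was chosen so soft tissue stays faint and cortical bone dominates, emulating
a bone X-ray rendering preset; only the six-point form, not the values, is
canonical, so the points are fully configurable. A Beer–Lambert alternative
(`mode = "attenuation"`, pixel $= 1 - e^{-\sum\alpha\,\Delta s}$) is provided
because screenshot-based DRR pipelines do not document their exact
compositing; the emission–absorption default reproduces the bright-bone
look. Parallel rather than cone-beam geometry is deliberate: it matches
orthographic-style captures, keeps closed-form test cases (a single opaque
voxel maps to exactly one pixel), and avoids unknown source geometry.

# X-ray preprocessing, packaging, splitting, augmentation

`preprocessXray()` applies eight steps in order: grayscale conversion
(channel mean), a brightness threshold, 3×3 opening then 5×5 closing,
largest 8-connected foreground component (ties broken by topmost-leftmost
bounding box), cropping of the original grayscale to that component's box,
min–max normalization (an all-constant crop collapses to zeros), symmetric
zero padding to a square (odd remainders at bottom/right), and bilinear
resampling to 128². Otsu's threshold is the default because DRR histograms
are near-bimodal and it needs no parameter; a fixed-quantile threshold is
available. The morphology kernel sizes are free choices; 3×3/5×5 are the
smallest pair that removes isolated speckle yet bridges one-pixel gaps.

`packageCase()` stores each case as a single serialized file with exactly
three elements — `ct` (normalized), `xray1`, `xray2` — with an exact round
trip; RDS is the package's native container for these records.
`splitCases()` shuffles under a seed and assigns the first
`round(0.8 n)` (half-up) cases to training, so 440 cases split into 352/88.
`augmentSample()` resizes both views to 150², takes a shared random 128²
crop, and standardizes by supplied mean/sd (identity by default; whether
such statistics should be dataset-level or fixed constants is genuinely
open, so they are explicit arguments).

# The two-view fusion GAN

The generator runs one dense 2D encoder per view (two 3×3 convolution
blocks per scale with a concatenative skip, four scales N…N/8). At the
three coarsest scales a 1×1 convolution matches channels and the 2D map is
replicated along the view's own projection axis into a pseudo-3D grid,
refined by a 3×3×3 block. Each view decodes with kernel-2 stride-2
transposed convolutions and skip connections; the lateral stream is rotated
90° about z into the anterior frame by an exact lattice rotation and
averaged element-wise with the anterior stream at each scale, feeding a
third decoding stream that emits the final `volumeSize`³ grid through a
sigmoid. Blocks are Conv + InstanceNorm + ReLU; the output head starts with
small weights and a dark bias so the sigmoid begins un-saturated near the
background intensity. The discriminator is a conditional 3D patch critic —
3×3×3 stacks with instance normalization, no dropout, mean-pool
downsampling — conditioned by concatenating each X-ray replicated along its
own projection axis as extra volume channels; it emits a (N/4)³ grid of
real/fake scores.

Losses (all exposed as plain functions and tested against loop oracles):

- **LSGAN**: $L_D = \tfrac12\,\overline{(d_\text{real}-1)^2} +
  \tfrac12\,\overline{d_\text{fake}^2}$,
  $L_{G,\text{adv}} = \overline{(d_\text{fake}-1)^2}$.
- **Reconstruction**: voxel MSE between generated and ground-truth volumes.
- **Projection**: mean over the three axes of the MSE between axis-mean
  projections; volumes differing only within projection rays score zero.
- **Feature matching**: mean absolute difference of the discriminator's
  intermediate activations for real versus generated input, averaged over
  layers.
- **Identity**: implemented as an input-consistency term — MSE between the two input X-rays and the
  corresponding axis-mean projections of the generated volume. It can be
  disabled (`wIdt = 0`).

The total generator objective is the weighted sum with defaults
`wGan = 0.1, wRecon = 10, wProj = 10, wFm = 10, wIdt = 5` (the term names are canonical for this
model family; the weights are free parameters, and these defaults encode
"reconstruction-dominant with a light adversarial prior" — everything is
configurable). Optimization is Adam (lr 2e-4, β₁ 0.5, β₂ 0.99), batch
size 1, with the learning rate constant for the first half of the epochs and
then decaying linearly towards zero — per-epoch updating admits many
schedules; linear decay is the documented choice here.
Training is fully seeded (initialization, data order, augmentation) and
aborts with the offending term's name if any loss goes non-finite.

Everything runs on a small reverse-mode autodiff engine written for this
package (convolutions lowered to cached gather + BLAS matrix products, with
the backward-data pass expressed as a convolution with the tap-flipped,
channel-transposed kernel). Every layer's analytic gradient is verified
against central finite differences in the test suite.

## Desk-scale training

`deskGanConfig()` captures the configuration used for CPU sanity runs:
32³ output, base width 4, 38 epochs over four phantom pairs (152 generator
updates), lr 2e-3, and weights
`wGan = 0.1, wRecon = 10, wProj = 10, wFm = 1, wIdt = 0.5`, with
augmentation off. The rationale: after ~150 updates the discriminator's
features are still close to their random initialization, so a heavy
feature-matching weight adds gradient variance without signal; crop jitter
slows four-sample memorization; and the full-scale learning rate of 2e-4
cannot move the parameters appreciably in 150 Adam steps. A desk run probes
the optimization machinery — losses falling, the model out-predicting the
mean-of-training-volumes baseline — not generalization. Full-scale runs
should use the defaults (`ganConfig()`), 128³ output and wider channels.

# Evaluation suite

Eleven statistics per ground-truth/reconstruction pair, averaged with a
plain mean over a set:

- `MAE0`/`MSE0`: per-slice mean absolute/squared error on the normalized
  scale, averaged over axial slices.
- `MAE`/`MSE`: whole-volume errors after denormalizing by the intensity
  scale. On cubic volumes `MAE = scale × MAE0` and `MSE = scale² × MSE0`
  exactly.
- Cosine similarity of the flattened volumes.
- `PSNR-1/2/3`: per-slice PSNR averaged along the axial (z), coronal (y) and
  sagittal (x) stacks respectively (the axis-to-index assignment is a
  documented convention). Per-slice values are averaged **after** the dB
  transform; that reading is what makes the per-plane average differ from
  `PSNR-3D`, the single PSNR of the whole volume. Zero-MSE cases are capped
  at 100 dB so reports stay finite.
- `SSIM`: mean over axial slices of 2D Gaussian-windowed SSIM (window 11,
  σ 1.5, K₁ = 0.01, K₂ = 0.03, dynamic range 1), with reflective borders.
  A windowed 3D SSIM is the other defensible reading for volumes;
  slice-averaged 2D is implemented here, and the window is exposed
  (`winSize`) because the 11-pixel default is wider than the 4³–8³ volumes
  used in oracle tests. Slices smaller than the window raise an error.

`angleSweep()` regenerates each test case's lateral DRR at angles
90/85/80/75° (anterior fixed at 0°), reruns preprocessing and
reconstruction, and tabulates one metric column per angle — the harness for
studying sensitivity to non-orthogonal biplanar geometry. It accepts any
`function(xray1, xray2[, case])` as the model, so stubs can exercise the
plumbing independently of training.

# Numerical choices and degenerate inputs

- PSNR cap: 100 dB for zero MSE (identity pairs), applied per slice and per
  volume.
- Min–max rescales that encounter a constant image return zeros (DRR emits a
  warning; preprocessing treats a constant crop as zeros by convention).
- Split sizes use round-half-up, making 440 × 0.2 = 88 exact.
- Ties for the largest connected component break towards the
  topmost-leftmost bounding box.
- The 90° lattice rotation used in fusion is exact (a permutation), so
  rotation/projection commutation holds to interpolation tolerance.
- Adam uses bias-corrected moments with ε = 1e-8; instance normalization
  uses ε = 1e-5.

# Problem sizes in the test suite

The shipped tests run the whole chain at reduced size, as their own
configuration choice: phantoms at 64³, networks at 16³/32³ with base widths
2–4, a single 128³ forward pass at width 2, metric oracles on 4³–8³ random
volumes, and the desk training run above. The pipeline demo configuration
(`inst/extdata/pipeline_small.yaml`) mirrors this scale.

# Known limitations

- The phantom's realism gap (above) bounds what green tests imply about
  clinical data; no real-data results are claimed anywhere in this package.
- Clinical-grade reconstruction quality requires real segmented spine CT
  cohorts and GPU-scale training; it is out of reach at desk scale by
  construction and deliberately not a target of the test suite.
- The DRR is parallel-beam and detector-physics-free; scatter, beam
  hardening and perspective are out of scope.
- HDF5 is a common container for paired samples in this problem domain; this
  package's native case format is RDS with the same three-element contract,
  as no HDF5 bindings are available in its dependency footprint.
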