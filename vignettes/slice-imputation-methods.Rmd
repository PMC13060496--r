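---
title: "Slice imputation for anisotropic slab reconstructions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice imputation for anisotropic slab reconstructions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

3D reconstructions built from photographs of coronal brain slabs are highly
anisotropic: roughly 1 mm resolution within each coronal plane, but 4-12 mm
between planes (the slab thickness, which may also vary slab to slab). The
missing through-plane detail degrades everything downstream - segmentations
become blocky, the cortical ribbon breaks up, surfaces look voxelated.
`slabimpute` fills the gap by synthesizing the missing coronal slices on a
fixed 1 mm anterior-posterior (AP) grid.

## Model

Each output coordinate is treated independently. Given the two nearest
observed slices $x_1$ (anterior) and $x_2$ (posterior) at distances $d_1$
and $d_2$ (mm) from the target, with $d = d_1 + d_2$ the slab thickness,
the linear interpolation

$$y_{lin}(x_1, x_2, d_1, d_2) = \frac{d_2}{d} x_1 + \frac{d_1}{d} x_2$$

is already a reasonable predictor, and the model only learns the residual:

$$\hat{y} = y_{lin}(x_1, x_2, d_1, d_2) + S_\theta(x_1, x_2, d_1, d_2),$$

where $S_\theta$ is a 2D U-Net. The network input has four channels:
$x_1$, $x_2$, and the two distances replicated into constant planes
(in mm, unnormalized - the trained range 2-12 mm is narrow enough that no
distance scaling is needed). Working slice-by-slice keeps memory small,
accommodates arbitrary and non-uniform slab thickness (each query carries
its own $d_1, d_2$), and avoids the volumetric hallucination that 3D losses
can introduce.

Key consequences, which the test suite asserts exactly:

* the decomposition is exact - with the output head zeroed, `impute_slice()`
  equals `linear_interpolate()` bit for bit;
* at $d_1 = 0$ the baseline returns $x_1$ itself;
* on any volume whose intensity is an affine function of the AP coordinate,
  $y_{lin}$ is exact, so decimating and re-imputing such a volume is lossless.

### Architecture

Four encoder stages of two units each - Group Normalization, a 3x3
convolution (zero-padded, "same" size), a Leaky ReLU (slope 0.01) - with
2x2 max pooling between stages; each stage halves resolution and doubles
channels. The bottleneck reaches $16 \times$ the base width: 1024 channels
at the default base width of 64. The decoder mirrors the encoder with
bilinear (interpolation-based) upsampling and concatenated skip
connections; a 1x1 convolution with no activation produces the residual
(which may be negative). Inputs must be divisible by 16 in-plane; other
sizes are mirror-padded and cropped back.

Three in-the-open design choices deserve a note:

* **The first unit applies no normalization.** Group-normalizing the raw
  4-channel input would map each constant distance plane to a constant
  (its group statistics are degenerate), erasing the distance conditioning
  the model depends on. Normalization starts after the first convolution
  has mixed the channels.
* **The output head is zero-initialized.** An untrained network then
  predicts exactly the linear baseline, which is both the natural residual
  starting point and the frozen reference that trained networks are
  compared against.
* **Group count.** Group Normalization uses 8 groups, capped at (and
  adjusted to divide) the channel count - a stable default at batch sizes
  where batch statistics would be noisy.

The engine itself (forward pass, backpropagation, Adam) is a compact
single-precision CPU implementation in C++ (RcppArmadillo); convolutions
are im2col + BLAS GEMM, and the large per-iteration buffers are reused
across iterations to keep the memory system quiet.

## Synthetic training data

Training pairs of real thin/thick photograph stacks do not exist, so the
network trains purely on synthetic data seeded by 3D label maps
(segmentations). Domain randomization makes every nuisance factor - shape,
contrast, brightness, slab geometry - so variable in training that the
network transfers to real data without retraining. Per training iteration,
one synthetic volume is generated and 32 triplets are digitally slabbed
from it:

1. **Geometry**: a random affine (rotation +-15 degrees, anisotropic scale
   0.85-1.15, shear +-0.1, translation +-10 mm) composed with a smooth
   random displacement field (amplitude drawn from 0-4 mm). The
   displacement field varies *faster along the AP axis* (correlation
   lengths 5 mm AP vs 20 mm in-plane), mimicking the imperfect slab-to-slab
   registration of real photograph reconstructions. Labels are resampled
   nearest-neighbor (they are categorical).
2. **Appearance**: each voxel draws its intensity from a Gaussian whose
   (mean, sd) depend only on its label; the parameters themselves are
   uniform draws (means 0-255, sd 0-25) per volume. Gamma augmentation
   (exponent $e^u$, $u \sim U(-0.3, 0.3)$, applied to min-max normalized
   intensities) skews the distributions; a smooth multiplicative
   illumination field (log-gain sd 0.2, correlation 8 mm AP / 32 mm
   in-plane, again faster along AP) emulates uneven slab lighting.
3. **Digital slabbing**: a random thickness $d \sim U(2, 12)$ mm, a random
   start $a$, and a random target offset $d_1 \sim U(0, d)$ produce the
   triplet $(x_1, x_2, y)$ by linear interpolation of the 1 mm grid at the
   continuous coordinates $a$, $a+d$, $a+d_1$. $x_1$ and $x_2$ are single
   extracted planes, not thickness-averaged slab faces.

Smooth random fields are built by sampling white noise on a coarse node
grid whose per-axis spacing equals the requested correlation length and
linearly upsampling - cheap, and the AP-faster-variation requirement is
enforced by construction. The empirical autocorrelation half-width
(`field_autocorr_halfwidth()`) verifies the anisotropy on every seeded draw
in the test suite.

None of the numeric randomization ranges are canonical; they follow the
conventions of segmentation-synthesis generators in this family and are
all exposed in `synth_config()`.

### What the phantoms do and do not model

`generate_phantom()` supplies label volumes (folded "cortex" shell around a
"white matter" core with an optional "ventricle") so the entire pipeline
runs with zero downloads. The sinusoidally folded shell reproduces the one
geometric property that matters here - thin, curved structure that slab
decimation visibly destroys. Phantoms do *not* contain real neuroanatomy,
light reflections, blood traces, uneven slab thickness within a stack, or
non-Gaussian intensity distributions; passing tests therefore demonstrate
correctness of the machinery and learnability of the synthetic task, not
clinical-grade performance on photographs.

## Loss and training

The loss on a predicted slice is

$$\mathcal{L} = \mathrm{MAE}(n(\hat{y}), n(y)) + \lambda\,
  \mathrm{MAE}(|\nabla n(\hat{y})|_{Sobel}, |\nabla n(y)|_{Sobel}),$$

with Sobel magnitudes computed with the standard 3x3 kernels under
edge-replicating boundary handling, and $\lambda = 1$ by default
($\lambda$ is not dictated by anything deeper than equal weighting; it is
configurable). A constant slice normalizes to zeros by convention - every
normalization step in the package shares that degenerate rule.

Normalization and the training frame deserve precision. Each triplet is
normalized *before both the forward pass and the loss*: $x_1$, $x_2$ and
the target $y$ are mapped through the joint min-max of $(x_1, x_2)$
(joint, so the relative brightness of the two slices survives, and the
same statistics are available at inference time). $y_{lin}$, the network
prediction, and the target then live in one shared frame, and the training
loss compares them directly there - which keeps the loss gradient exact
(the package's backward pass is verified against central finite
differences). The user-facing `imputation_loss()` and `validate()` are
evaluation metrics and normalize each slice independently per the formula
above; since min-max normalization is invariant to affine intensity maps,
the validation MAE is unaffected by the choice of training frame. At
inference the residual is mapped back through the inverse of the joint
normalization, and predictions are clipped to the observed intensity range
of the two bounding slices - out-of-range intensities after adding a
residual have no physical meaning here.

Optimization is Adam (beta 0.9/0.999, eps 1e-8). Two named profiles ship
with the package:

* `"full"`: learning rate 1e-6, 1000-slice frozen validation set,
  open-ended iteration budget - the full-scale schedule;
* `"desk"`: learning rate 1e-4, 100-slice validation set, 500 iterations -
  converges on one CPU in minutes and is the profile used by
  `scripts/acceptance.R`.

Validation slices are generated once under the run seed and frozen -
resampling them would destabilize both early stopping and the
best-checkpoint selection. "Until convergence" is operationalized as: no
validation improvement greater than 1e-5 for 10 consecutive checks. The
parameters with the best validation MAE are the ones returned, and the
initial parameters are validated as checkpoint 0 - with the zero-head
init that checkpoint *is* the linear baseline, so a run in which learning
fails returns the baseline rather than something worse.

The test suite scales further down where runtime budgets demand it: the
multi-seed learning check trains each of 5 seeds for 200 iterations (other
settings unchanged), and smoke tests use base width 4 on 32x32 slices.
These sizes are stated here as the package's own test-design choices.

## Volume inference

`plan_imputation_grid()` enumerates the arithmetic 1 mm target grid
spanning the observed AP range, anchored at the first observed slice
(where the grid sits relative to slab faces is a convention; anchoring at
the first slice keeps observed coordinates on-grid for uniform stacks).
Each target maps to its two bounding observed slices; targets within
1e-6 mm of an observed coordinate are *passthrough* - the observed image is
copied verbatim, never predicted. There is no extrapolation beyond the
first or last observed slice: behaviour outside the observed span is
undefined for a model trained on interior slabs, and the known weakness of
edge slabs (only one informative input) argues for conservatism. Slabs
thicker than the trained 2-12 mm range produce a warning but are imputed -
the distance conditioning may extrapolate, and the user is told.

RGB stacks are processed one channel at a time with identical distance
queries (joint multi-channel modeling adds cost without demonstrated
benefit); imputation therefore commutes with channel permutation, which is
asserted as a property test.

## Evaluation metrics

* **Dice**: $2|A \cap B| / (|A| + |B|)$ per label; 1 if the label is absent
  from both volumes (flagged), 0 if absent from exactly one. Dice requires
  a shared grid; `resample_labels_nn()` is provided but never applied
  implicitly, since resampling changes scores.
* **Closest-point surface distance**: per source vertex, the distance to
  the nearest point on the reference triangle set (point-to-triangle; the
  nearest point is either an interior projection or on a boundary segment,
  and the implementation takes the minimum over both). The measure is
  asymmetric and both directions are exposed; reported tables use the
  reconstruction-to-reference direction. Parcel summaries are means of
  parcel means - every labeled area counts equally regardless of vertex
  count.
* **Cortical thickness**: one-directional white-to-pial closest-point
  distance; thickness errors compare parcel means, so meshes of different
  topology can be compared through a shared parcellation.

Sphere fixtures (`make_sphere_mesh()`, a subdivided icosahedron) provide
analytic references: concentric spheres of radii 10 and 12 must yield
distances of 2 mm within the tessellation sagitta (< 0.03 mm at three
subdivisions).

## Numerical conventions, in one place

* Constant slice under min-max normalization -> all zeros, everywhere.
* Passthrough coordinate tolerance: 1e-6 mm.
* Nearest-neighbor warps round half away from zero; out-of-volume sources
  become background.
* Slice extraction at integer AP coordinates returns the stored slice
  without arithmetic (bit-exact passthrough of the generator's grid).
* The network computes in single precision; exported parameters and
  checkpoints round-trip bit-exactly (float to double to float is exact).
* All samplers are pure functions of the R global RNG state; `set.seed`
  makes every pipeline stage replay bit-identically on the same hardware
  and thread settings.

## Known limitations

Desk-scale training margins are small: with 200-500 CPU iterations the
trained network undercuts the linear baseline by a fraction of a percent
of validation MAE - enough to demonstrate learning, far from the
improvements a full-scale training run provides. The generator does not
model specular reflection or wet-tissue artifacts. Thickness uses a
one-directional closest-point definition rather than a surface-normal
formulation. Inference loads the whole stack into memory, which is
comfortable at photograph-reconstruction sizes but not for micron-scale
volumes.
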