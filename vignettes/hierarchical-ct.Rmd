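---
title: "Hierarchical learned reconstruction for parallel-beam CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical learned reconstruction for parallel-beam CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierct)
```

## The problem

Tomographic reconstruction maps a sinogram — the collection of line
integrals $p(r, \theta)$ of an attenuation image $f(x, y)$ along rays with
radial offset $r$ and view angle $\theta$ — back to the image. As a linear
inverse problem its forward model is a Fredholm integral with the ray kernel
$\delta(x\cos\theta + y\sin\theta - r)$. The transform is non-local: every
detector reading depends on a full line of pixels, and every pixel
influences half of the sinogram. A neural network that modeled the
$512^2 \to 512^2$ transform with a dense layer would need $512^4 \approx
7\times10^{10}$ weights, which is why purely data-driven reconstruction
networks have historically been limited to very small images.

`hierct` implements a hierarchical decomposition of this transform. The key
object is the *partial line integral*
$$
q_\alpha(r, \theta, t) \;=\; \frac{1}{\alpha}
  \int \Pi\!\left(\frac{s - t}{\alpha}\right)\, f\big(u(r,\theta,s)\big)\,
  \mathrm{d}s ,
$$
the integral of $f$ along the ray $(r, \theta)$ restricted by a rectangular
window of width $\alpha$ centered at depth $t$ (stored divided by $\alpha$,
i.e. as mean attenuation over the window, so intermediate data and image
voxels share units). The sinogram is the marginal case $\alpha =$ field of
view with a single depth bin; the image is the marginal case $\alpha =$ one
pixel with a single view angle, because at $\theta = 0$ the $(r, t)$
coordinates coincide with $(x, y)$. Shrinking $\alpha$ step by step,
$\alpha_1 > \alpha_2 > \dots > \alpha_N$, turns the one-shot inversion into
a sequence of *local* refinements: each step gains depth resolution while
the angular sampling thins, keeping the total data volume constant. The
elementary step is a limited-angle (tomosynthesis-like) reconstruction:
coarse depth information about a segment of a ray is recoverable from rays
at nearby angles that pass through it.

## Stage schedules

`plan_schedule()` discretizes the $\alpha$-continuum. Depth-bin counts grow
by a factor of 4 per step (the first step adjusted so the product reaches
the image size), the angle count shrinks to conserve $N_t N_\theta N_r$, and
the radial bin count is held fixed. For the full-size configuration of 512
channels, 512 angles over 360°, and a 512×512 image, five stages result:

```{r schedule}
plan_schedule(512, 512, 512)
```

Non-power-of-two sizes round the depth counts and conserve data volume only
approximately; `validate_schedule()` reports non-integer resampling ratios
and data-size drift as warnings (the layers learn the resampling), and
violations of the hard invariants — monotone depth growth, monotone angular
decimation, correct marginal stages — as errors.

## Sparse-connection layers

Each stage transition is one linear layer that stores and trains only the
weights inside a small neighborhood, by default 3 depth bins × 5 angles × 3
radial bins. The layer is a sparse matrix; the forward pass multiplies the
input by it, backpropagation multiplies by its transpose.

The neighborhood anchor deserves care, and is the one place where this
package had a genuinely open design decision. Consecutive stages index
their data in *rotated* coordinate frames: stage data at view angle
$\theta$ live on an $r$–$t$ grid rotated by $\theta$. The package therefore
anchors connections **geometrically** (`anchor = "geometric"`): each output
cell gathers from the bins of its `d_theta` nearest input frames that
contain the output cell's physical position, re-expressed in that input
frame. This is the tomosynthesis stencil — an output cell draws on the rays
that actually pass through it at neighboring view angles — and it makes the
elementary refinement step representable with local weights. The simpler
alternative of rescaling each index proportionally (`anchor =
"proportional"`, also provided) ignores the frame rotation; away from the
rotation center its neighborhoods point at the wrong physical location, and
with ratio-4 depth steps it leaves output cells with no connections at all.
The `init_backprojection()` construction below only exists under geometric
anchoring.

Two accounting facts, both computed by `count_params()` without
materializing the patterns: the five-stage full-size configuration carries
about 43 million sparse weights — 0.06% of the $512^4$ dense equivalent —
and across image sizes the total scales as $O(n \log n)$ in the pixel count
$n$, because each of the $O(\log n)$ stages holds $O(n)$ weights.

## The analytic parameterization

Because the gather stencil can express interpolation at rotated positions,
the architecture admits a closed-form weight assignment that performs
classical filtered backprojection hierarchically: the filter layer takes
the discrete ramp kernel scaled by the backprojection weight $\pi/N_\theta$,
and each sparse layer assigns every input view angle to its nearest output
frame with bilinear interpolation weights at the rotated position. The
accumulated sector backprojections become the full reconstruction at the
final stage. `init_backprojection()` installs these weights; on held-out
ellipse phantoms the resulting network matches the package's own FBP
reference to within a few percent in RMSE. This provides a correctness
proof of the architecture, a reference point for trained models, and clean
impulse-response demonstrations: a unit impulse fed into the final stage
maps to a short depth segment whose orientation follows the partial image's
view angle.

## Training protocol

Training is supervised, with mean squared error and minibatch (size 20)
stochastic gradient steps throughout:

1. **Noise-pattern data.** `gen_noise_dataset()` draws white Gaussian
   images (standard normal per pixel; the scale is immaterial for a linear
   operator under MSE) and pairs them with their exact forward projections.
   Such pairs encode the transform itself free of any image prior. The
   default is 200 realizations.
2. **Intermediate labels.** `make_intermediate_labels()` produces per-stage
   targets either by full-data FBP onto each stage's anisotropic $r$–$t$
   grid (depth spacing $\alpha$, radial spacing one channel; the default)
   or by reprojecting the images over partial line integrals.
3. **Stage-wise pretraining.** `pretrain_stagewise()` trains each sparse
   layer alone on (previous-stage label → stage label) pairs, bringing the
   all-ones initial weights to a sensible magnitude. The level-0 data are
   the sinograms themselves, so the first layer is pretrained jointly with
   the sinogram filter layer. Pretraining never changes the final loss
   definition.
4. **End-to-end training.** `train_end_to_end()` minimizes image-domain MSE
   only. To sidestep vanishing gradients through the deep linear chain,
   exactly one layer — picked uniformly at random per iteration — is
   updated while the rest stay frozen. Noise training runs in linear mode;
   no nonlinearity is present anywhere, so the learned operator is provably
   linear (superposition is asserted in the tests).
5. **Nonlinear refinement.** `refine_nonlinear()` switches on an
   image-domain convolution block (3×3 kernels, ReLU hidden layers,
   Glorot-initialized) and continues end-to-end training on pairs made by
   reprojecting structured images — synthetic random-ellipse phantoms stand
   in for clinical scans — with additive Gaussian sinogram noise (standard
   deviation expressed as a fraction of the maximum sinogram value, default
   1%). The block is a residual correction head: its output is added to the
   linear reconstruction, so an untrained block perturbs rather than
   replaces it.

Step sizes are the one training quantity the protocol leaves open. Fixed
global rates are impractical here: the all-ones initialization gives the
layers curvatures differing by orders of magnitude. In linear mode the loss
restricted to any single layer is exactly quadratic, so each update steps
along the stochastic gradient by the closed-form minimizing step size, with
the configured rates acting as damping factors (1 = full step; 0 freezes a
layer). Convolution layers, where ReLU breaks the quadratic structure, use
a backtracking step size instead. Validation uses structured phantom
images rather than noise; when a validation set is supplied,
`train_end_to_end()` returns the weights with the best validation loss seen.

## What the synthetic generators do and do not emulate

The generators supply everything the package consumes: white-noise training
images, random-ellipse phantoms (closed-form Radon transforms make them a
projector oracle independent of ray tracing), the standard ten-ellipse head
phantom, and additive Gaussian sinogram noise. They deliberately do not
model anatomy, photon statistics (Poisson noise, dose), detector physics,
beam hardening, scatter, or non-parallel geometries. Passing tests
therefore demonstrate correctness of the operators and the training
machinery under an idealized parallel-beam model — not clinical image
quality.

## Numerical choices

* Projector: exact ray/pixel-intersection lengths (incremental Siddon-style
  traversal in compiled code), so forward projections are exact for
  piecewise-constant images; partial line integrals clip the traversal to
  each depth window, and windows tile the ray exactly.
* FBP filter: frequency-domain Ram-Lak ($|\omega|$), no apodization, FFT
  zero-padded to the next power of two at least twice the radial length;
  backprojection uses linear interpolation, with weight $\pi/N_\theta$ for
  both 180° and (redundant) 360° spans. The small DC bias this filter
  carries at modest grid sizes is accepted for bit-reproducibility.
* Coordinates: pixel centers at $-\mathrm{fov}/2 + (i - 0.5)\Delta$, rays
  parameterized by offset from the rotation center and counter-clockwise
  angle from the +x axis, depth bins tiling $[-\mathrm{fov}/2,
  \mathrm{fov}/2)$ half-open. Anisotropic-grid FBP averages the
  reconstruction over each depth window (up to 8 sub-samples).
* Index rounding maps continuous bin positions with halves rounded toward
  the lower index, stated for reproducibility.
* Neighborhoods clip at depth and radial boundaries and wrap periodically
  in angle, capped at the number of distinct angles.
* All randomness flows through explicit integer seeds; phantoms, noise
  datasets and training runs are pure functions of their seeds.

## Scaled study conditions and known limitations

The test suite exercises a scaled configuration — 64×64 images, 64 angles,
a 3-stage schedule, 50 noise pairs, linear mode; training completes in a
few minutes on one CPU — and a smaller 32×32 variant for the training
machinery. Two properties of the full-size protocol do not carry down to
this regime, and the acceptance checks that assert them fail honestly
rather than being weakened:

* At 50 training pairs the end-to-end objective is underdetermined (about
  2×10⁵ scalar equations against 3.5×10⁵ sparse weights), and each output
  neuron's regression sees roughly as many samples as it has incoming
  weights. Gradient training then drives the training loss toward zero
  while *degrading* held-out accuracy — started from the analytic
  parameterization it only moves away from it — so validation selection
  effectively preserves the pretrained starting point, whose label-fitting
  floor is several times the FBP error. The published protocol's ratio of
  samples to per-neuron weights (200 against ~45) sits in a different
  statistical regime than the scaled-down one.
* For the same reason the trained (as opposed to analytic) final-stage
  impulse responses spread a substantial fraction of their energy beyond
  the ideal depth-segment footprint.

The architecture itself is not the limitation: the analytic
parameterization reaches FBP-level accuracy, and all operator-level
properties (oracle agreement, conservation, adjoint consistency, linearity,
parameter scaling) hold tightly. Training quality at full scale, with the
published data sizes and compute budgets, is outside what this package's
test conditions can demonstrate.
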