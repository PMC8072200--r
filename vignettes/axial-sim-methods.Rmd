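---
title: "Methods: simulating, reconstructing and learning axial super-resolution in hexagonal SIM"
author: "AxialSIM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, reconstructing and learning axial super-resolution in hexagonal SIM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

AxialSIM implements an end-to-end computational study of axial
super-resolution in structured illumination microscopy (SIM): it simulates
raw 7-frame hexagonal SIM stacks and high-resolution confocal-style target
stacks from 3D point-cloud specimens, reconstructs the raw stacks with the
classical Wiener band-separation algorithm, trains a modified residual
channel attention network (RCAN) to map SIM chunks directly to
confocal-quality output at twice the lateral and three times the axial plane
density, and quantifies resolution with an autocorrelation-based FWHM
estimator. This vignette documents the models, the numerical choices and the
design decisions, and states what the synthetic data can and cannot show
about real microscopes.

## Specimens

Two specimen families drive all simulations.

* **Sphere-bounded clouds** — `generateSphereCloud()` draws emitters
  uniformly inside a ball (default radius 5 µm) by rejection sampling from
  the enclosing cube, which is exact (no polar-coordinate density
  distortion). The mean emitter radius of a uniform ball is 3R/4, which the
  test suite verifies by Monte Carlo.
* **Chromatin-like structures** — `generateChromatinCloud()` emulates a
  dense, filamentous, laterally bounded chromatin mass as a confined 3D
  random walk with fixed step length (default 50 nm), bounded in a 16 × 16
  µm square laterally and ±2 µm axially, with an emitter at every vertex.
  Steps that would exit the bounds are redrawn rather than reflected: this
  preserves both the confinement and the exact step length between
  consecutive emitters, which reflection would shorten. The walk is a
  deliberately minimal surrogate for a polymer model: it reproduces the
  density, connectivity and lateral boundedness that matter for
  training-data statistics, not chromatin physics.

Emitter counts are not part of the optical model and are exposed as
configuration; the defaults are 5000 (chromatin) and 1000 (sphere), chosen
so chromatin stacks are dense enough for strong neighbour cross-correlation
while spheres probe the sparse regime. `readSmlmCsv()` imports SMLM-style
localization tables (header with `x`, `y`, `z`; nm or µm) for evaluation on
third-party structures; coordinates are re-centred on the bounding-box
midpoint.

## Optical model

`opticsConfig()` fixes the simulated microscope: NA 1.1, shared
illumination/emission wavelength 525 nm, 60× magnification, a 256 × 256
camera of 6.5 µm pixels (sample-plane pixel 108.33 nm), 40 focal planes at
dz = 250 nm. The PSF is scalar: a uniform circular pupil with paraxial
defocus phase `exp(-i * pi * lambda * d * k^2)`, evaluated by FFT per
defocus. Scalar paraxial theory is approximate at NA 1.1, but it reproduces
the classical lateral width 0.51 λ/NA within a few percent (verified against
direct pupil integration) and keeps every OTF analytic where the
reconstruction needs it. Vectorial effects, aberrations and camera read
noise are out of scope.

The illumination is the interference of three unit-amplitude coherent beams
whose lateral wavevectors sit at 120° spacing on a circle of radius NA/λ,
giving a hexagonal pattern with six carrier frequencies of magnitude
√3·NA/λ plus DC — the same carrier set as a 2-beam 3-angle setup. Frame
`f` (0..6) advances the phases of beams 2 and 3 by `2*pi*f/7` and
`6*pi*f/7`. The integer multipliers (0, 1, 3) matter: the six pairwise beam
differences then acquire frame factors `exp(2i*pi*f*d/7)` with
`d = ±1, ±2, ±3`, so the 7 × 7 frame–band mixing matrix is a unitary DFT
matrix — exactly invertible, and the 7-frame sum is exactly uniform (21
everywhere), a property the renderer and the reconstruction both rely on
and the tests verify to 10⁻⁶. Multiplier pairs such as (1, 2) collide
(`+1` and `+2-1` bands share a frame factor) and would make separation
singular.

The illumination is delivered as a thin light-sheet from the side: a
Gaussian axial envelope (default FWHM 700 nm, chosen near the detection
axial resolution so sheet and detection contribute comparably) multiplies
the emitter brightness per plane. The axial envelope is truncated where it
falls below 10⁻³ of its peak.

**Rendering** is done per plane in Fourier space. Emitters are binned on a
fine axial grid (dz/3 ≈ 83 nm by default); each occupied slice contributes
a phase-ramp field `sum_j c_j exp(-2i*pi*k·x_j)` evaluated at the emitters'
*continuous* lateral positions (a BLAS complex matrix product), multiplied
by the slice's defocused OTF and the sheet envelope. This avoids
voxelization bias entirely: the rendered image equals samples of the exact
band-limited continuous image, up to periodic wraparound (lateral boundary
handling is periodic). Linearity and integer-pixel translation equivariance
are exact and tested. Sub-resolution negative ringing (below ~10⁻⁶ of the
peak, from spatial wraparound of PSF tails) is clamped to zero.

The **high-resolution confocal target** images the same cloud with the
square of a widefield PSF computed at λ/2, on the doubled lateral grid
(54.17 nm pixels) and 3 × 40 = 120 planes at dz/3 — the resolution goal the
network trains toward, doubling both lateral and axial resolution. The
squared-PSF spectrum extends slightly beyond the fine-grid Nyquist limit;
the sub-Nyquist tail carries negligible energy and is truncated. The axial
support is adaptive: slices are included while their defocused energy
exceeds 10⁻³ of focus.

**Poisson noise** (`addPoissonNoise()`) rescales a stack so a unit-weight
emitter at best focus yields the requested photon budget over its 7 frames
(the noise-free renderer delivers exactly 21 illumination units there, so
the calibration is analytic), then draws each pixel from a Poisson law.
Levels of 2048 and 16 photons per emitter bracket the high-SNR and
extreme-noise regimes of the robustness sweep.

## Classical reconstruction

`reconstructSim()` implements Gustafsson-style processing adapted to the
7-frame hexagonal geometry, with constant parameters matched to the
simulation (no parameter estimation from data — estimation is imprecise on
sparse point clouds, and fixing parameters removes that variability):

1. per plane, FFT the 7 frames and invert the unitary mixing matrix to
   separate the DC band and six carrier bands;
2. zero-pad each band's spectrum to the doubled grid and shift it to its
   true carrier frequency with a sub-pixel real-space phase ramp;
3. combine with a generalized Wiener filter whose weights are the shifted
   analytic in-focus OTFs (`chat` function), with a scalar regularizer
   (default 10⁻³ of the peak summed squared OTF), and a triangle
   apodization to the extended cutoff (2 + √3)·NA/λ;
4. interpolate the 40 output planes to 120 by Fourier zero-padding along z
   (band-limited; introduces no axial structure), and clamp residual
   negative ringing at output only.

Because the Wiener denominator and apodization are analytic, each band's
combined weight is evaluated directly in the band's own coordinates, so the
whole per-plane recombination needs one inverse FFT per band. The
reconstruction is linear before the final clamp; a single-emitter
reconstruction halves the widefield lateral FWHM within 15%, and energy
beyond twice the widefield cutoff stays below 10⁻⁴ of the total.

## Resolution metric: autocorrelation FWHM

`estimateFwhm()` measures resolution from every point source at once: the
3D autocorrelation (inverse FFT of the power spectrum) is normalized at
zero lag, the profile through zero lag is extracted (axial: the on-axis z
profile; lateral: the radial average of the central plane), and a sum of
two Gaussians is fit by bounded least squares (`minpack.lm`). The narrow
Gaussian models the autocorrelation of individual PSFs; the broad one
absorbs the cross-correlation of neighbouring, randomly placed emitters
(which is why the estimate is stable from sparse to dense specimens —
tested to agree within 10% across a 36-fold density change).

Numerical choices:

* The volume mean is subtracted before the power spectrum. Without this the
  DC term adds a constant pedestal that a two-Gaussian model cannot
  represent.
* The reported FWHM converts the narrow ACF width back to the image domain:
  the autocorrelation of a Gaussian of width σ has width σ√2, so
  `FWHM = 2*sqrt(2*log 2) * sigma_min / sqrt(2)`. This makes the estimator
  exact on synthetic bead volumes with Gaussian PSFs (tested at σ = 100,
  200, 400 nm to within 5% of 2.355σ).
* Fit bounds enforce the narrow/broad identifiability: σ ∈ [1, 20] voxel
  spacings for the narrow term, [2, 200] for the broad term, amplitudes
  ≥ 0. The FWHM is taken from the narrowest component whose amplitude is at
  least 5% of the total — a vanishing-amplitude component's width is
  unidentified and must not drive the estimate.
* Profiles are fit per axis (not to the full 3D ACF); up to 64 one-sided
  lag samples enter the fit. On large reconstructions the package's
  drivers analyse a central 256-pixel lateral window, which keeps the 3D
  FFT affordable without changing the local statistic.

`imageMse()` and `imageSsim()` provide fidelity metrics; SSIM uses an
11-sample Gaussian window (σ = 1.5), the standard stabilizing constants
(K₁ = 0.01, K₂ = 0.03) with the reference volume's range as dynamic range,
window statistics over the valid interior, averaged per z-plane. Volumes
are min-max normalized before comparison in the drivers, since the network
works in per-chunk normalized units.

## Training data

`chunkStack()` slices a SIM/target pair into chunks of 3 consecutive SIM
planes (21 input frames → 9 output planes). Two planes are trimmed at each
stack end first: the simulated stacks carry little signal there, and the
trim reconciles the chunk count to 12 per 40-plane stack
(`floor((40 - 4)/3)`), i.e. 1656 pre-filter datapoints from 138 stacks.
`filterLowSignal()` then discards chunks below a mean-pixel threshold of
10⁻⁷ (chunk level) or whose per-plane image groups all fall below 5·10⁻⁷
(pair level) — both thresholds are exposed because the two printed values
operate at different granularities. `normalizeChunks()` min-max scales each
chunk's input and target to [0, 1] independently, storing the factors for
de-normalization; per-chunk (rather than per-stack or global) scaling means
inference needs no dataset-level statistics. The train/test split reserves
whole stacks (10 chromatin + 20 sphere by default) before any training;
validation is carved from the remaining chunks at a 10% fraction, matching
the study's ~130 validation points out of ~1300 post-filter chunks.

## Network

`buildRcan()` constructs the modified RCAN: the first convolution is 3D
(kernel 3³) over the interleaved (plane, frame) input axis ordered
plane-major, so the first layer can mix adjacent SIM images within a chunk
before the 2D residual machinery; its output is flattened to 2D feature
maps and projected to the feature width. Then `nGroups` residual groups,
each of `nBlocks` residual channel-attention blocks
(conv–ReLU–conv + squeeze-and-excitation channel attention with bottleneck
ratio `reduction`, plus a block skip), a group convolution and skip, a long
skip over all groups, a 2× sub-pixel (pixel-shuffle) upsampler, and an
output convolution to 3 planes per input SIM image. The published-scale
configuration is 12 groups × 3 blocks with 64 features and reduction 16;
feature width and reduction are not printed in the source study and follow
the RCAN lineage defaults. Activation (ReLU), zero padding and He-normal
initialization are conventional defaults, all seeded.

There is no deep-learning framework in the package's dependency set: the
layers (im2col convolutions on BLAS matrix products, channel attention,
pixel shuffle) and their backward passes are implemented directly, and
every layer's gradient is verified against central finite differences in
the test suite (relative error ~10⁻⁹).

`trainRcan()` minimizes per-chunk MSE with Adam (the optimizer is not named
in the source study; Adam with default moments is the conventional choice,
config-exposed), gradient components clipped to ±0.1, starting learning
rate 10⁻⁶ by default, multiplied by 0.5 when validation has not improved
for 10 epochs (the plateau mechanism's constants are not printed; both are
config-exposed) and additionally by 0.99 every 5 epochs. The
best-validation parameters are checkpointed. Negative output values —
small, normally distributed errors on zero-valued background — are
truncated at inference (`inferRcan()`), equivalent to a final ReLU without
its gradient cost.

The package's test surface trains a reduced model (2 groups × 2 blocks, 16
features) on small chunks: toy smoke-training uses 16 × 16 chunks, and the
matched toy experiment uses 32-pixel stacks of small chromatin structures
(400 emitters, 3 µm box, ±1 µm axially, 16 planes). These sizes keep a full
CPU training run in the minutes range while exercising the identical code
path as the published-scale configuration. Training at published scale
(1178 chunks of 256² input, ~8 h on two GPUs in the source study) is
supported by the same functions but is not part of the test surface, and
the published trained weights are not reproduced; the package's claim is
the qualitative one, verified end-to-end: a reduced RCAN trained to
convergence on matched synthetic data yields a smaller axial FWHM than the
classical reconstruction on held-out stacks.

`ablateInputChannel()` implements the channel-masking ablation: one of the
7 SIM frames is zeroed across all planes, inference is re-run, and the
degradation is reported against both the unmasked output and the
high-resolution reference. Note a toy-scale caveat: for a converged
full-scale model every frame carries useful information and masking any
frame worsens MSE and SSIM, but minutes-scale toy models do not reliably
show this inequality (masking can act as a crude regularizer on an
under-trained network), so the package's tests assert the ablation
mechanics rather than the inequality.

## What the simulations do and do not show

The synthetic data reproduce: diffraction-limited widefield detection with
defocus, hexagonal 7-frame structured illumination with exact component
separability, light-sheet axial confinement, shot noise, and the
point-cloud character of the training specimens. They do not reproduce:
vectorial high-NA effects, optical aberrations, refractive-index mismatch,
camera read noise or EMCCD gain, photobleaching/blinking, continuous
(non-point) fluorophore distributions, or pattern estimation errors (the
reconstruction uses the exact simulation parameters by design). Passing
tests therefore demonstrate correctness of the algorithms and the
qualitative resolution relationships on this model family — not performance
on experimental data, where the network's tendency to reconstruct dense
continuous structures as discrete points (an artefact of point-cloud
training data) is a known limitation.

## Reduced problem sizes used by the test surface

Unit tests run at 64- or 32-pixel cameras with 8–16 planes, where every
optical property (uniform frame sum, linearity, equivariance, band
separation) holds exactly as at full scale. The acceptance computation
renders five full-scale chromatin stacks (256² × 40 planes, 5000 emitters)
and reconstructs them to 120 × 512² before measuring the axial FWHM over a
central 256-pixel window; dataset bookkeeping runs the full 168-specimen
recipe at a 32-pixel camera with the axial geometry (40 planes, dz 250 nm,
±2 µm specimens, 700 nm sheet) at true scale, since the low-signal
filtering it checks is an axial phenomenon. These sizes are the package's
own choices for a deterministic, CPU-friendly test surface.
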