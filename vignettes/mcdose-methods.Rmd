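---
title: "Denoising Monte Carlo dose distributions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising Monte Carlo dose distributions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: what each component
models, which choices were genuinely open and how they were settled, and
what the synthetic benchmark does and does not demonstrate about clinical
data.

## The denoising problem

A Monte Carlo (MC) dose distribution estimated from `N` particle histories
carries per-voxel statistical noise whose relative standard deviation
scales as `1/sqrt(N)`. A "fast" calculation (order 1e6 histories) finishes
in seconds but is dominated by noise; a "reference" calculation (order
1e8) takes hours. The package trains a two-channel 3D U-net to map the
fast, high-uncertainty dose plus the CT to the low-uncertainty dose, and
evaluates the result with the dosimetric metrics of the field: global
gamma analysis, masked RMSE, ISNR and DVH parameters.

No clinical data ships with the package. Everything is exercised on a
synthetic cohort whose *statistical* structure matches MC dose; the dose
*physics* is deliberately simple (below).

## The synthetic cohort

**Phantoms.** Water-equivalent ellipsoidal bodies (HU 0) in air
(HU −1000), with optional lung-like (−700 HU) and bone-like (+700 HU)
ellipsoidal inserts, on a 0.25 × 0.25 × 0.25 cm grid — the working voxel
size of the whole pipeline. The body mask is derived as HU > −400 and is
the hard support of all dose grids ("dose outside the body is deleted").

**Clean dose engine.** Each VMAT-like arc is a set of control points
(gantry angle, MU weight, rectangular aperture half-widths at the
isocenter, collimator rotation, energy label ∈ {6, 10, 15} MV) around an
isocenter at 100 cm source–axis distance. Per control point the dose is

    mu_c · T_c(v) · exp(−μ(E) · d_rad(v)) · (SAD / dist(v))²

with `T_c` the rotated rectangular aperture convolved with an isotropic
Gaussian penumbra (an exact separable product of error-function edge
profiles), `d_rad` the ray-marched radiological depth (density from HU by
the linear map −1000 → 0, 0 → 1 g/cm³), and the last factor the
inverse-square divergence. Per-energy constants are fixed plausible
monotone trends — attenuation 0.050/0.045/0.040 cm²/g and penumbra sigma
0.4/0.5/0.6 cm for 6/10/15 MV. The engine produces arc-like dose
morphology (a high-dose core around the isocenter with angular spreading)
and is fully deterministic; it makes no claim to transport physics — no
scatter, no buildup, no spectral effects. Magnitudes are nominal Gy/MU.

The public `radiological_depth()` marches with a default step of one
quarter of the smallest voxel dimension (the contract allows up to one
half); the dose engine uses the half-voxel step, adequate for a smooth
exponential attenuation, and exposes `depth_step` for finer quadrature.

**Noise model.** A noisy realization multiplies each voxel by a unit-mean
Gamma variate with shape

    k_v = k0 · N · D(v) / max(D)

so the relative standard deviation is `1/sqrt(k_v)`: heteroscedastic,
non-negative, exactly zero where the dose is zero, and following the MC
`1/sqrt(N)` law by construction. The calibration `k0 = 1/(0.6² · 1.5e6)`
puts the default fast setting (1.5e6 histories) at ≈ 60% relative noise at
the maximum-dose voxel (≈ 70% averaged over the >50%-of-max reporting
region), and a 200× larger history count — the fast/reference ratio — at
≈ 5%. Statistical uncertainty (SU) is reported, per the usual convention
in the MC dose literature, as the mean relative standard error over voxels
receiving more than 50% of the maximum mean dose.

The training target is the engine's deterministic dose — the ideal
zero-noise reference. A finite-history "low-SU" member can be drawn with
`sample_noisy_dose()` at a large `N` when a noisy reference is wanted.

**Augmentation.** Variants of each base arc re-randomize: per-control-point
MU by a multiplicative jitter in [0.2, 2] renormalized to a total MU drawn
in [0.5, 2] × the base total (the source description randomizes MU without
stating ranges; these are the package's choices); the energy uniformly
from {6, 10, 15} MV; the isocenter by a bounded per-axis shift
(±9/±5/±10 cm envelope at clinical scale, scaled to the phantom for the
desk-scale benchmark), rejected and resampled up to 100 times until it
falls inside the body; and the collimator rotation uniformly. Aperture
shapes are never modified — variants keep realistic beam shapes. Every
draw is recorded in a roster tibble that round-trips losslessly through
JSON (17 significant digits).

## The network

The denoiser is an encoder–decoder with skip connections at every
resolution level. "Four layers" is realized as four down-sampling steps,
i.e. five resolution levels with a doubling width ladder (32, 64, 128,
256, 512 at production scale). Each level applies two 3×3×3 same-padded
convolutions with ReLU (optional batch normalization). The first pooling
is 3×3×1 — arcs are coplanar and dose gradients along the rotation axis
are steep, so z resolution is kept through the first level — and deeper
poolings are 2×2×2. Upsampling is a learned transposed convolution with
kernel equal to the pooling stride (3×3×1 at the top, 2×2×2 below), which
exactly inverts the irregular first pool; skip features are concatenated
before the two decoder convolutions, and a final 1×1×1 convolution maps to
one channel. With two input channels, z-size 64 and no batch
normalization, `count_parameters()` gives 22,578,241 ≈ 2.2578×10⁷; a
four-level (three-pool) reading gives ≈ 2.24×10⁷ and cannot reproduce that
count, which settled the depth question. The closed-form count is checked
against the instantiated network (sum of weight-array lengths) for every
candidate configuration.

Weight initialization is fan-in He Gaussian with a seeded generator;
biases start at zero. The five candidate configurations (z ∈ {32, 64, 96},
one or two input channels, batch normalization on or off) are all
constructible; the z = 64, two-channel, no-batch-norm candidate is the
production model. The candidate-selection experiment itself is not
reproduced.

Forward and backward passes are implemented natively: direct 3×3×3
convolutions in C++ (chosen over im2col + GEMM because the desk-scale
networks are narrow, making im2col memory-bound), explicit
backpropagation for every layer, and Adam in R. The backward pass is
verified against central finite differences; the test perturbs biases off
zero first because zero-initialized biases put dead 3³ neighbourhoods
exactly on the ReLU kink, where a central difference measures the
half-slope rather than the subgradient the analytic pass uses.

Batch normalization uses per-sample spatial statistics in training mode
(the optimizer processes samples singly, accumulating gradients to the
batch size) and running statistics in evaluation mode.

## Training protocol

Case-level splitting (80/10/10 by CT, so no phantom appears in two splits)
precedes everything; every triplet inherits its case's split. Training
draws one random patch per triplet per epoch (the epoch definition is
unstated in the source description; one patch per volume keeps epoch
semantics well defined), applies independent mirror coin-flips per axis
and a random multiple-of-90° rotation in the xy plane (rotations about z
only — the same coplanarity argument as the pooling), and optimizes the
summed-squared-error loss with Adam at 1e-4, batch size 2. After each
epoch the validation loss is evaluated on deterministic central patches;
"improvement" is a strict relative decrease by more than 1e-8. The
learning rate is divided by 5 after 4 consecutive non-improving epochs
(counter resets on improvement and after each decrease — standard plateau
semantics); training stops after 30 consecutive non-improving epochs; the
returned weights are those of the best validation epoch, not the last.

Input and output channels are scaled by dataset-level constants: per
calibration case the maximum absolute value (CT shifted by +1000 HU first,
so air maps to zero and a single positive factor lands the channel in
[0, 1]), averaged over cases. For *applying* the scaling the package uses
the power-of-two ceiling of each constant: dividing and re-multiplying by
a power of two is exact in IEEE arithmetic, which makes the entire
preprocessing chain exactly invertible — the identity-network test
demonstrates bit-exact round-trips through scale → crop/pad → patch →
overlap-average → unscale → mask. The ceiling is within a factor 2 of the
calibrated constant, so the scaled range remains approximately [0, 1].

## Inference

Volumes wider than the network footprint are cropped centrally in x and y
(on an odd surplus the extra voxel is removed from the high-index side);
narrower volumes are zero-padded symmetrically (extra pad voxel on the
high-index side). Volumes taller than the z input are processed in the
minimal number of z-patches, the first anchored at 0 and the last at
`z − patch_z`, intermediate corners spaced evenly; overlapping voxels are
averaged with equal weights (the stride/overlap at inference is unstated
in the source description; the equalized minimal-count layout is the
package's documented choice, and weighted aggregation is out of scope).
Negative network outputs are clipped to zero and everything outside the
body mask is zeroed. Whole plans are denoised by summing the per-field
noisy doses first and denoising once — matching the workflow of one fast
calculation per field followed by a single denoising of the plan dose.

## Evaluation suite

**Gamma.** Global normalization (dose criterion as a percentage of the
maximum *reference* dose), 10% low-dose threshold restricting both the
gamma map and the pass-rate denominator (the conventional reading),
reference-point-centred search over the evaluated distribution with
trilinear interpolation on a grid of one tenth of the distance criterion
within a radius of three times the distance criterion. Offsets are scanned
in order of increasing distance and the scan stops once the distance term
alone exceeds the running minimum; a test verifies the optimized search
against an exhaustive direct-formula oracle to 0.01 in gamma. An optional
`max_gamma` cap bounds the scan on badly disagreeing pairs; any cap above
1 provably cannot change pass/fail classification (a passing candidate
lies within one distance criterion of its voxel). Voxels exactly on the
criterion boundary pass (1e-9 relative tolerance), so a uniform +2% offset
passes 2%/2 mm at 100%. Tighter criteria never pass more voxels; the suite
asserts gamma-2 ≤ gamma-3 throughout.

**RMSE** is reported over voxels above 10% of the maximum reference dose
(the variant actually reported for dose grids; the all-voxel variant is
the `threshold_fraction = 0` option). `whole_treatment_rmse()` translates
a per-MU RMSE to a treatment course: `rmse × MU per fraction × number of
fractions`; 1.19e-4 Gy/MU × 300 MU × 25 fractions = 0.89 ≈ 0.9 Gy.

**ISNR** is the decibel ratio `10·log10(MSE(noisy)/MSE(denoised))` against
the reference (the MSE-ratio definition; an exactly-zero denoised error is
signalled as an unbounded-improvement condition rather than returned as a
number).

**DVH.** Cumulative curves at 0.01 Gy default bin width; `Dx%` is linearly
interpolated between bins; `Vx%` is evaluated against an absolute dose
level (x% of the prescription) over the body mask by default,
switchable to any structure mask; `Dm` is the arithmetic mean dose.

## The desk-scale benchmark

The end-to-end workflow (`run_end_to_end()`) at its defaults is the
package's benchmark: 6 phantoms of 48³ voxels (12 cm cubes at 0.25 cm), 15
base arcs of 8 control points, augmentation factor 4 (60 triplets), noisy
members at 1.5e6 histories, a width-4 U-net (same depth and pooling as the
production architecture, 353,353 parameters), 48×48×16 patches, at most 30
epochs. The desk-scale run uses Adam at 1e-3 rather than the full-scale
1e-4: Adam's step size is bounded by the learning rate regardless of loss
scale, and a 30-epoch budget of ~720 updates is two orders of magnitude
short of the full-scale schedule the 1e-4 rate presumes; the rate is a
`workflow_config()` parameter, and `train_config()` keeps the full-scale
default. These problem sizes are the package's benchmark choices; the
suite runs the whole chain in roughly a quarter of an hour on one CPU.

On held-out cases this benchmark reaches a median ISNR well above 10 dB
(an order-of-magnitude MSE reduction), and the trained network beats the
identity map on validation loss — the margins the acceptance suite
asserts. It does *not* reproduce clinical pass rates: the simulator's
dose morphology is far simpler than clinical VMAT dose, the network is
~64× narrower, and the cohort ~50× smaller.

One finding deserves emphasis because it contradicts a natural
expectation. The *gamma* pass rate of the raw noisy input against the
clean reference is near 100% at this noise level — higher than the
denoised result's (~90%). Global gamma is almost blind to voxel-wise
noise in the *evaluated* distribution: the search interpolates the
evaluated dose over a radius of several voxels, and a field with ~60%
relative white noise sweeps through the reference value somewhere within
the distance criterion at nearly every voxel. A smooth denoised output,
by contrast, pays at every voxel where it carries a small spatially
correlated bias that no distance search can repair. "Denoised gamma
exceeds noisy gamma" is therefore not attainable under these conditions —
not because denoising fails (the ISNR shows a ~20-fold MSE reduction) but
because gamma is the wrong instrument for quantifying noise; the suite
keeps the comparison as an explicitly failing check and leans on ISNR and
RMSE as the discriminating metrics. This leniency of gamma toward noisy
evaluated distributions is a known property of the metric, and is also
why dose-grid comparisons conventionally report RMSE alongside gamma.

## Numerical choices and degenerate inputs

- Scale/unscale uses power-of-two constants (exact inversion, above).
- Conservative resampling interpolates the per-axis cumulative integral
  with a monotone cubic Hermite (Fritsch–Carlson) curve and differences it
  on the target grid; endpoints are interpolated exactly, so the total
  integral is conserved to 1e-6 relative by construction. The physical
  extent is kept fixed; the target voxel size is adjusted to the nearest
  size that tiles it. A target coarser than the whole extent errors.
- Crop tie-breaks: left-biased retained window on odd surplus, extra pad
  voxel on the high-index side on odd deficit (documented because
  "centrally" alone does not fix the parity).
- Master-seed fan-out hashes stage names with a polynomial rolling hash
  modulo 2³¹−1, so one workflow seed yields independent, reproducible
  per-stage seeds below R's integer ceiling.
- Degenerate inputs error loudly: all-zero reference distributions,
  empty structures, empty field lists, sources inside the body,
  isocenters outside it, non-finite losses, bodies too small to admit an
  isocenter shift (after 100 rejection attempts).

## Known limitations

- The dose engine is analytic plumbing, not transport physics: no scatter,
  no electron disequilibrium, no buildup region, no spectral hardening.
- Gamma supports the fixed working grid (equal voxel spacing per axis as
  written by the simulator); local-dose-difference variants are not
  implemented.
- Batch-norm training statistics are per-sample (batch of one at gradient
  time); the production candidate does not use batch normalization.
- The CLI is a thin wrapper for the workflow and file-level operations;
  clinical I/O (DICOM-RT plans, treatment-planning-system integration) is
  out of scope.
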