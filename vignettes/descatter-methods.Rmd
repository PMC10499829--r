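---
title: "Models and methods behind descatter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind descatter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the physical and statistical models the package
implements, the numerical choices behind them, and what the test suite does
and does not establish. It is the design record: where a choice was genuinely
open, the rationale is given here.

## The imaging model

A patterned-excitation wide-field two-photon measurement of an object
`X0(x, y, z)` (non-negative fluorophore density on a voxel grid) is modelled
in four stages:

1. **Patterned excitation.** A binary pattern `H_t(x, y)` is projected onto
   the focal plane. The pattern is treated as a two-dimensional sheet at the
   focal plane, so its three-dimensional convolution with the excitation PSF
   makes the excitation field slice at axial offset `dz` from the focus equal
   to `H_t *₂D exPSF(·, ·, dz)`. Two consequences matter: the pattern
   contrast blurs away from the focal plane at the rate set by the PSF's
   axial profile, and the total excitation falls off with defocus — which is
   exactly the optical sectioning that temporal focusing provides. (The
   alternative reading, replicating `H_t` along z before convolving, makes
   the excitation independent of z and removes sectioning altogether; it is
   not physical and is not used.)

2. **Object interaction and per-depth scattering.** The excited object
   (excitation × `X0`, element-wise) emits at a shorter wavelength; each
   plane of the emission is convolved in 2-D with the scattering PSF *for
   its own depth below the tissue surface*. The object carries its axial
   position relative to the surface (`origin_z`), and each plane picks the
   scattering kernel whose simulated depth is nearest.

3. **Emission blur and focal-plane extraction.** The scattered volume is
   convolved in 3-D with the emission PSF and the focal plane is extracted.
   Since only one plane is kept, the implementation evaluates exactly the
   terms of the 3-D convolution that land on the focal plane (a sum of 2-D
   convolutions over the emission PSF's axial support); this is
   mathematically identical to the full 3-D convolution followed by slicing
   and is checked against a brute-force spatial-domain convolution in the
   tests.

4. **Detection.** The focal-plane image, scaled by `photons_per_unit`
   (expected photoelectrons per intensity unit; default 5, which puts
   isolated bright features at a handful of photons — the regime a deep
   measurement actually operates in), passes through the EMCCD model below.

All convolutions are zero-padded "same" convolutions computed by FFT (padded
to fast composite sizes, centre-cropped). Zero padding bounds wrap-around
error; tests that compare against spatial-domain convolution hold to 1e-6
relative.

The paired training target (the "unscattered reference") is the object
convolved in 3-D with the excitation PSF, evaluated at the focal plane —
the image a point-scanning two-photon microscope of the same optics would
record.

## Point-spread functions

The instrument's PSFs are not part of this package's contribution, so they
default to the standard separable Gaussian approximation of a
diffraction-limited focus: lateral width
`sigma_xy = 0.325 * lambda / (sqrt(2) * NA^0.91)` and axial width
`sigma_z = (0.532 * lambda / sqrt(2)) / (n - sqrt(n^2 - NA^2))`, both in
micrometres. For two-photon excitation the intensity profile is squared
before normalization (narrowing each axis by `sqrt(2)`). Defaults are NA 1.0
water immersion (n = 1.33), 1.036 um excitation and 0.58 um emission (a
rhodamine-like vascular label). Any user-supplied PSF volume can be passed
instead — `psf_volume()` only enforces non-negativity, unit mass and a
centred peak — so vendor-calculated or measured PSFs drop in without
touching the forward model.

## Monte Carlo scattering PSF

The scattering PSF at depth `z0` answers: for a point emitter `z0` below the
surface, where does the collected light *appear* to come from on the
emitter's own plane? Photons are launched from `(0, 0, -z0)` and propagated
as in standard photon-transport practice:

- free path `s = -ln(1 - rnd1) / mu_s` (exponential with the scattering
  coefficient);
- deflection cosine sampled from the Henyey–Greenstein phase function with
  anisotropy `g` (inverse-CDF form, isotropic limit at `g = 0`);
- azimuth uniform on `[0, 2*pi)` — the convention of the photon-transport
  literature; a normally distributed azimuth would bias the scattered
  distribution and has no physical basis;
- the final hop is truncated exactly at the surface `z = 0`; the exit
  direction is the direction of that hop;
- acceptance inside the objective cone is tested in tissue,
  `sin(theta_exit) <= NA / n_tissue`; no refraction at the surface is
  modelled;
- accepted photons are traced straight back along their exit direction to
  the plane `z = -z0` and binned there.

Launch directions are isotropic over the *upward* hemisphere. In an
absorption-free semi-infinite medium, downward-launched photons re-enter the
acceptance statistics only after long diffusive excursions that contribute
vanishingly to the collected image; the reported acceptance fraction is
halved so it still refers to emission over the full sphere, and the
`launch = "full"` option restores the literal 4π launch. There is no
absorption (`mu_a = 0`), matching the model's scope. Photons still inside
the medium after `max_hops = 300` scattering events are terminated and kept
in the acceptance denominator; at the depths used here (up to 7 scattering
lengths) no accepted photon history approaches that cap, which was verified
by raising the cap and observing identical images.

Defaults `mu_s = 0.02 um^-1` (scattering length 50 um at the emission
wavelength) and `g = 0.9` are typical cortex values; both are arguments.
The binning grid defaults to the object's lateral grid; accepted photons
landing outside it are discarded but counted in the denominator, so deep
halos that extend past the field of view lose mass to truncation — a
deliberate choice that mirrors what a finite-field camera sees. Images are
normalized to unit sum after binning, and the acceptance fraction is stored
separately.

## EMCCD detection

Detection draws, per pixel, a Poisson shot count with the expected signal,
adds a Poisson dark count (`dark_mean`, in electrons per pixel per
exposure), multiplies the sum through the electron-multiplication register,
and adds Gaussian read noise. The register is parameterized by the mean gain
`g_EM` and the number of stages `N` (defaults 300 and 512 — the register
length of common cameras); the per-stage success probability is solved as
`alpha = g_EM^{1/N} - 1 ≈ 1.1%`, inside the 1–2% range such registers
operate at. Each stage adds `Binomial(x, alpha)` electrons to its input `x`.
The excess-noise factor of the cascade,
`F^2 = 2 (g_EM - 1) g_EM^{-(N+1)/N} + 1/g_EM -> 2` at high gain, is exposed
as a closed form, and the tests verify the detector's empirical mean and
variance against `mean = g_EM * lambda` and
`var = g_EM^2 F^2 lambda + sigma_read^2` on a grid of photon levels.

Cascading every pixel through 512 binomial stages is too slow for dataset
simulation, so the cascade's output distribution is tabulated per input
count. Because the register acts on each input electron independently, the
output for `x` electrons is distributed as the sum of `x` independent
single-electron outputs; the table is therefore built from a pool of
single-electron cascades (row `x` = row `x-1` plus a fresh single-electron
draw), which is exact in distribution and two orders of magnitude faster
than cascading each row jointly. The joint method remains available
(`method = "direct"`) and a two-sample Kolmogorov–Smirnov test in the suite
confirms the two are indistinguishable. Inputs above the table limit fall
back to direct cascading. Read noise can make individual pixels negative;
they are left unclipped because clipping would bias the mean law.

A deterministic `noise_free = TRUE` mode replaces the cascade by its mean
and draws no noise (output exactly `g_EM ×` input); the forward-model
reduction tests use it.

## Phantoms

**Beads.** Two populations of spheres — small bright (radius 1.5 px,
intensity enhanced 5×) and large dim (radius 6 px) — with per-bead base
intensities from Normal(1, 0.1) truncated at zero. Placement is uniform with
rejection on centre distance (no overlaps); spheres are rasterized with a
one-voxel linear coverage ramp because binary rasterization aliases badly at
1.5-px radii. Bead load is either an areal density (default 3 beads per
100×100 px², which keeps a 256² field in the 10–30 bead range of sparse bead
preparations) or explicit per-volume counts; the scaled-down learning
experiment uses counts (6 small + 3 large per 64² volume) so that the
*per-image* bead count, not the areal density, matches the sparse fields the
full-size configuration produces.

**Vessels.** A seedable random-walk tube grower: each tube follows a
direction random walk (step 2 px, angular perturbation sd 0.25), with radius
uniform in 1–7 px and an intensity that grows with radius, so the stated
post-processing — thresholding at a fraction of the maximum (default
190/255, i.e. an 8-bit threshold of 190), optional isotropic rescale by a
configurable factor (trilinear), normalization to maximum 1 — removes the
finest, dimmest vessels as intended. This generator is a synthetic stand-in
for downloadable vascular volumes: it reproduces their stated statistics
(radius range, thresholding, normalization), not their anatomy.

**Sub-volume extraction** from any supplied stack clips intensities at a
ceiling (default 20), slides an axial window with a stride (default 5
planes), and keeps windows whose mean strictly exceeds a gate (default: the
global mean of the clipped stack). The strict inequality means a perfectly
uniform stack yields no windows — ties are excluded by construction.

## The inverse network

The de-scattering network maps the T patterned measurements (channels) to
one image. It is an encoder–decoder with `2L + 1` double-convolution blocks
(`L = 4` levels by default, giving 9 blocks): each block is
[3×3 conv → batch norm → ReLU] twice; 2×2 max-pool downsampling; skip
connections concatenate encoder features into the decoder; after every
decoder block a concurrent spatial-and-channel squeeze-and-excitation block
reweights the features, with the two gate maps combined element-wise by max
(the variant its authors recommend; reduction ratio 2). Upsampling is
nearest-neighbour followed by a 1×1 convolution — chosen over bilinear
interpolation for its exact, cheap adjoint in the hand-written backward
pass, in the spirit of the original UNet's learned up-convolution; the
choice is recorded in the configuration. The terminal reconstruction block
is a 3×3 convolution to one channel and a ReLU, so outputs are non-negative
by construction.

The implementation is pure R on BLAS with two small C++ kernels (the im2col
gather of 3×3 patches and its transpose); feature maps are dense matrices
(pixels × channels) so convolutions become GEMMs. Every layer's analytic
gradient is verified against central finite differences through the entire
network in the test suite — that test, not trust in a framework, is what
certifies the training loop.

**Losses.** Four are provided: MSE; RMSLE computed as the root mean square
of `log(1+x)` differences on zero-clipped images (the standard convention —
a raw logarithm is undefined at the zero background these images are full
of); smooth-L1 as the element-wise Huber with threshold 1 (quadratic below
unit error, linear above — the gate is per pixel, not on the mean error,
which would make the loss discontinuous in aggregate); and KL divergence,
for which prediction and target are shifted by 1e-8 and normalized to sum
to one per image, since relative entropy is defined between distributions.
KL is the default.

**Normalization.** Each measurement stack is divided by its own 99.9th
percentile and each target by its maximum; both factors are stored in the
stack and reapplied at inference, so reconstructions can be reported in
physical units. Networks need bounded inputs, and the KL loss needs the
target on a scale where its implicit distribution is meaningful.

**Training.** Adam with learning rate 1e-3, betas (0.9, 0.999), batch 10,
100 epochs by default (all overridable; an optional geometric learning-rate
decay to `lr_final` is available). Shuffling, initialization and noise all
derive from named sub-streams of one seed, so training is bit-reproducible;
the best-validation-loss parameters are kept. A non-finite loss aborts with
a diagnostic rather than training on.

## Metrics

SSIM follows the standard windowed statistic with `C1 = (0.01 L)^2`,
`C2 = (0.03 L)^2`, `L = 1`: an 11×11 Gaussian window (sigma 1.5) by default,
with uniform and single-window ("global") variants — the global variant
admits closed-form checks on constant images, and the windowed
implementation is verified to 1e-6 against an independent brute-force
sliding-window evaluation. Population (not sample) moments are used, and
windows are evaluated where they fit entirely inside the image. PSNR uses
the per-pair peak of the reference image by default. Cohort evaluation
reports mean ± sd with MSE in 1e-4 units and SSIM in 1e-2 units, the
conventional reporting scales.

## Problem sizes, determinism, and what the tests show

The suite and the acceptance script run at desk scale, a deliberate
configuration of the same code paths the full-scale study would use:
Monte Carlo checks at 1e5–1e6 photons; detector laws at 2e4 pixels per
photon level; and the learning experiment at 100 bead stacks of 64×64 with
8 patterns, base width 16, 20 epochs of KL training, with the focal plane 4
scattering lengths deep. At this scale the trained network's held-out SSIM
exceeds the average-of-measurements baseline by a wide margin (the
acceptance script recomputes both numbers). The full-scale configuration
(3455 stacks of 256×256, 32 patterns, 100 epochs) is exposed as
`default_config(preset = "full")` and runs the identical pipeline; it is a
multi-hour computation and is validated structurally, not executed, in the
suite.

Passing tests establish that the simulator obeys its sampling and noise
laws, that the forward operator is the stated convolution chain, and that
the inverse learns to undo *this simulator's* degradation on *these
phantoms*. They do not establish transfer to experimental measurements:
real tissue has depth-varying optics, refractive-index mismatch at the
surface, excitation-side scattering, and camera nonidealities (clock-induced
charge, smearing, saturation) that the model deliberately omits, and the
bead/vessel phantoms do not capture the texture of real neuronal or vascular
stacks. The package's role is to make those gaps explicit and configurable,
not to close them.

## Known limitations

- Scattering kernels are truncated at the binning grid; at many scattering
  lengths most accepted light lies outside any practical field of view, so
  unit-sum normalization redistributes that loss into the retained kernel.
- The medium is homogeneous and absorption-free; polarization, time of
  flight and Fresnel reflection are out of scope.
- Batch normalization couples samples within a batch; reproducibility is
  exact only for a fixed batch composition (which the seeded shuffling
  fixes).
- The R training loop is single-threaded; the desk-scale experiment trains
  in minutes, but the full-scale configuration wants hours and is better
  run on parallel BLAS.
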