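---
title: "Patient-specific distortion correction for SRS MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific distortion correction for SRS MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdcorrect)
```

## The problem

Gamma Knife stereotactic radiosurgery (GK-SRS) delivers a single high dose
with sub-millimetre dose gradients, so the MRI on which the plan is drawn
must be geometrically accurate to well under a millimetre. Magnetic
susceptibility differs between tissue (about −9 ppm, SI volume
susceptibility) and air (about +0.4 ppm), so air cavities in the temporal
bone and nasal sinuses perturb the static field B0 by parts per million.
During frequency encoding, an off-resonance Δf (Hz) at a voxel is
indistinguishable from a position offset, so the voxel's signal is displaced
along the readout axis by

    Δx = Δf / BW   pixels,   Δf = γ/2π · ΔB,

where BW is the per-pixel readout bandwidth. Vestibular schwannomas sit at
the internal auditory canal, next to the air-filled middle ear and mastoid —
exactly where this patient-specific distortion (PSD) is largest. The package
implements the full correction chain: field-map estimation from dual-echo
phase, displacement and Jacobian computation, intensity-compensated
unwarping, a convolutional predictor of the field map from anatomy alone,
and the geometric and dosimetric evaluation of what the correction does to
an SRS plan.

## Field map from dual-echo phase

Between echo times TE1 and TE2 the phase of a gradient-echo signal advances
by `Δφ = 2π·Δf·(TE2−TE1)`, hence `fieldmap_from_phase()` computes
`Δf = Δφ / (2π (TE2−TE1))` with echo times in ms (converted to seconds
internally); in Tesla, `ΔB = Δφ/(γ ΔTE)` with γ in rad/s/T. The measured
phase difference is wrapped into (−π, π]; `unwrap_delta_phi()` unwraps it
spatially by seeded region growing: starting from the highest-magnitude
voxel (or the voxel nearest the mask centroid), a front grows through the
mask and each new voxel receives the 2π multiple that brings it closest to
the mean of its already-unwrapped neighbours. The result is defined up to a
single global 2π multiple, which is irrelevant after the field map is
demeaned by the dipole convention below. Field maps are stored in Hz because
the displacement step consumes Hz/pixel directly; Tesla is a derived view
(`fieldmap_tesla()`).

Sign convention: positive Δf shifts signal toward increasing voxel index
along the readout axis when `polarity = +1` in `sequence_params()`. The
gradient polarity is not recorded in NIfTI headers, so it is an explicit
parameter rather than an inference.

## Displacement, Jacobian, and unwarping

Because the distortion acts along one axis, the Jacobian matrix of the
deformation is diagonal and its determinant reduces to
`det J = 1 + ∂(Δx)/∂x` along the readout axis, computed with central
differences in the interior and one-sided differences at the boundary
slices (`jacobian_determinant()`).

Two resampling operations are provided:

* `forward_warp()` *simulates* the distortion (used to build training and
  evaluation pairs): each output line samples the input at `x − Δx(x)` and
  multiplies by the exact derivative of that sampling map, `1 − ∂Δx/∂x`.
  Using the exact factor of the map actually applied (rather than a
  first-order reciprocal) makes total signal conservation exact up to
  interpolation error; the suite checks conservation to 0.5% for compactly
  supported objects.
* `unwarp()` is the correction: the distorted image is resampled at
  `x + Δx(x)` and multiplied by `det J = 1 + ∂Δx/∂x`, restoring intensities
  that were stretched or compressed. The two operations are mutual inverses
  to second order in Δx; the suite requires a round-trip NMSE ≤ 2% for
  smooth images with peak shifts of 2 px.

The displacement map is defined in the undistorted frame and assumed slowly
varying, so the same map serves both directions; with the fields the phantom
produces (|∂Δx/∂x| ≲ 0.7) the frame difference is second-order. Fold-over
(`det J ≤ 0`) is an error naming the first offending voxel, never a silent
clip: it signals nonphysical parameters (e.g. an unrealistically low
bandwidth). Interpolation is 1D Catmull-Rom cubic along the readout axis
(linear available), and out-of-field samples are zero-filled, matching the
air background.

Masks are transported with the same geometric transform, linear
interpolation and re-binarization at 0.5 (`warp_mask()`). Binarization makes
sub-voxel translations invisible — a constant 0.4 px shift returns the
identical binary mask — so the evaluation pipeline additionally transports a
fractional ("soft") copy of the target and measures centroid errors with
intensity-weighted centroids. This mirrors clinical contours, which are
drawn on continuous images and do move sub-voxel; Dice, Hausdorff, volume
and all dose metrics still use binary masks.

## The synthetic head phantom

The phantom (`make_head_phantom()`) replaces clinical data so that the whole
pipeline is buildable and testable offline. It emulates the features that
matter for the physics:

* a natural-scale ellipsoidal head of soft tissue (χ = −9.05 ppm) with a
  thin cortical bone shell (−11.4 ppm) in air (+0.36 ppm), on a 96³ grid at
  1.25 mm;
* on each side, the pneumatized temporal bone: an auditory canal entering
  laterally, a middle-ear cavity and petrous air cells at its medial end,
  and a mastoid air-cell complex behind it — together several cc of air,
  the susceptibility load that distorts the cerebellopontine-angle region —
  plus a nasal cavity;
* a roughly spherical hyperintense target of about 2.7 cc (randomized
  ±25%, matching reported vestibular-schwannoma volumes) abutting the
  medial end of the right canal;
* T1-like piecewise contrast, slightly Gaussian-smoothed (σ = 1 mm) to be
  band-limited, with a smooth multiplicative bias field and Gaussian noise.

Per-case geometric jitter (±12% on the air-cavity geometry, ±6% on the head
semi-axes — the head's shape sets a global demagnetization field whose
natural variation is modest) makes every seed a distinct anatomy with a
distinct induced field, which is what the predictor has to learn.
Generation is bit-exact reproducible under a seed.

The induced field is computed by the standard k-space dipole convolution,
`ΔB(k) = B0 · χ(k) · (1/3 − k_z²/|k|²)` with the k = 0 coefficient set to
zero (the field is defined up to a constant; this makes it zero-mean).
The χ-map is padded with the background susceptibility (≥ 32 voxels per
side) before the FFT to suppress wrap-around. Against the closed-form
exterior solution of a uniformly susceptible sphere,
`ΔB = Δχ·B0·a³(3cos²θ−1)/(3r³)`, the implementation is accurate to well
under 1% RMS outside a 2-voxel shell, improving with resolution. For the
forward distortion the χ-map is first smoothed by σ = 1.6 mm: real
air-tissue interfaces are band-limited by voxel partial volume, and a
perfectly sharp numerical interface would produce unphysical single-voxel
field gradients (and fold-over at clinical bandwidths). The stored χ-map
itself remains exactly piecewise.

At the default study conditions — 3 T, 220 Hz/pixel, 1.25 mm voxels — the
maximum in-brain displacement is 1.9–2.2 mm across seeds at the air
interfaces, and the target's contour centroid shifts consistently by a few
tenths of a millimetre along the readout axis, matching the in-vivo reports
for this anatomy (≈1.2 mm interface distortion, contour shifts up to
≈0.9 mm, a consistent centroid displacement along frequency encoding).

## The field-map predictor

The predictor is a patch-based 3D U-Net regressing the off-resonance map
(Hz) from the anatomical image: three ResNet encoder stages (3×3×3
convolutions, stride 2, with a 1×1×1 stride-2 projection on the residual
branch, channel width doubling per stage), a decoder of nearest-neighbour
upsampling followed by convolution (upsampling + convolution rather than
transposed convolution, which avoids checkerboard artifacts), skip
connections by channel concatenation, and an L1 loss trained with Adam
(learning rate 2×10⁻⁴, β = 0.9/0.999 by default). No pre-installed R
package provides trainable 3D convolutions, so the network is implemented
in the package itself: convolutions are lowered to matrix products computed
in single precision (im2col and SGEMM in C++; float32 is the standard
precision for network training and halves the memory traffic that dominates
CPU cost), backpropagation is hand-written, activations are leaky rectifiers
(slope 0.1; plain rectifiers occasionally killed units under batch-size-1
L1 training), and the analytic gradients are verified against central
finite differences in the suite.

Inputs are normalized per volume by a robust z-score (median/IQR inside the
head mask); field targets are scaled to unit spread by one global factor
estimated on the training set and recorded in the model manifest, and
predictions are rescaled to Hz. Whole-volume prediction tiles the volume
with 50% patch overlap and averages overlapping predictions; output is set
to zero outside the head mask with a 3-voxel inward feather, because a hard
step at the head boundary would put an artificial spike in the displacement
derivative and can fold the Jacobian during correction. Training, initialization and patch sampling
are fully seeded; identical seeds give identical weights.

Desk-scale defaults shrink the full-scale protocol so the whole experiment
runs on one CPU in minutes: 32³ patches instead of 64³, 8 base channels,
4 patches per volume, 9 epochs over 22 training phantoms, and a learning
rate of 10⁻³ decayed by 0.8 per epoch (with only about a thousand optimizer
steps, the reference rate of 2×10⁻⁴ would leave the model far from
convergence; the manifest records whichever values were used). Full-scale
values remain available through `net_config()`/`train_config()`. The epoch
with the best validation loss is kept, where validation is the whole-volume
L1 over the head of the held-out validation volumes — a patch-subsample
estimate proved too noisy to select models reliably.

## Dosimetric model and indices

GK-SRS plans are modelled as sums of isotropic Gaussian shots
(`simulate_gk_dose()`), globally scaled so that the maximum dose is
`rx / 0.5` — the prescription (12 Gy by default) is delivered at the 50%
isodose, the usual Gamma Knife convention. This is a deliberate
simplification of a treatment planning system; it reproduces the features
the indices measure (steep falloff, prescription isodose geometry) with a
closed form to test against: a single shot has GI = 2√2 exactly and its
prescription isosurface is the sphere `r = σ√(2 ln 2)`.

Indices on a target mask: DVH points (Dμ, Dmax, Dmin, D95% — the dose
received by at least 95% of the target, computed by voxel counting without
interpolation), target coverage `TC = TV_PIV/TV`, Paddick conformity
`PCI = TV_PIV²/(TV·PIV)` (the identity `PCI = TC · TV_PIV/PIV` holds
exactly by construction), gradient index `GI = V(rx/2)/V(rx)` with volumes
over the whole grid, and homogeneity index. HI defaults to `Dmax/rx`
(exactly 2 under 50%-isodose prescription); the ICRU-style
`(D2%−D98%)/D50%` variant is available because conventions differ.

Before/after comparisons use the two-sided Wilcoxon signed-rank test with
zero differences dropped: exact for up to 25 informative pairs via the
rank-sum distribution computed by dynamic programming over doubled midranks
(so ties are handled exactly; the suite checks agreement with brute-force
sign-flip enumeration), and a normal approximation with tie and continuity
corrections above that. `stats::wilcox.test` is not used because its exact
path refuses ties, which real metric tables contain.

The clinical dosimetric workflow — plan on corrected images, copy the
dose to the uncorrected geometry — is mirrored as: simulate the dose
targeting the corrected contour, then evaluate the same dose grid against
the corrected ("after") and uncorrected ("before") contours.

## The end-to-end experiment

`run_experiment()` chains everything: simulate `n_cases` phantoms, train on
a split, and for held-out cases predict the field from the distorted image,
correct image and contour, and tabulate geometric and dosimetric metrics
with the paired Wilcoxon comparison. One global seed derives per-stage
seeds by fixed offsets, so stages can be rerun in isolation; the manifest
(config, seeds, weight hash, package version) is sufficient to reproduce a
run. Correction with the *true* field (`oracle_correct()`) is always
evaluated alongside as the ceiling of the predictor path; the suite asserts
the oracle never scores below the predictor on Dice.

Desk-scale problem sizes, stated as the package's own defaults: 30 cases of
96³ voxels at 1.25 mm (22 train / 2 validation / 6 test). With those sizes
the full experiment takes roughly a quarter of an hour on one CPU, nearly
all of it training.

## What the phantom does and does not show

The phantom exercises every algorithmic property the pipeline relies on:
correct dipole physics, unit handling, invertibility of the warp, learnable
anatomy→field structure, and the full metric stack. It does not emulate MR
signal formation (no relaxation or sequence simulation), chemical-shift or
contrast-agent effects, scanner-specific gradient nonlinearity, inter-rater
contour variability, or the anatomical variability of real heads. Passing
the suite therefore demonstrates the correctness and reproducibility of the
machinery at reduced scale, not clinical performance; the headline clinical
numbers of a full-scale study (field-map NMSE near 6%, Dice near 0.90
between corrected and uncorrected contours, and so on) require real
multi-subject data and full-scale training and are out of scope here.

## Numerical choices and degenerate inputs

* Interpolation: Catmull-Rom cubic for images (edge-preserving at sub-voxel
  shifts), linear for masks; out-of-grid samples are zero.
* Zero displacement short-circuits to a bit-identical copy (the cubic
  weights are exactly {0,1,0,0} at integer positions).
* `det J ≤ 0` anywhere is an error; `make_distorted_pair()` translates it
  into advice to raise the bandwidth.
* NMSE refuses a zero-norm reference; Dice refuses two empty masks;
  Hausdorff and centroid refuse empty masks; DVH metrics refuse an empty
  target; `compare_plans()` refuses fewer than 5 informative pairs (the
  pipeline relaxes this to `NA` p-values for tied metrics such as a
  hot-spot Dmax both contours contain).
* The SSIM stabilizers follow the stated convention `c1 = 0.01·L`,
  `c2 = 0.03·L` (linear in the dynamic range) in the default global mode;
  the conventional windowed form with squared constants is available via
  `mode = "windowed"` since both conventions appear in the literature.
* Hausdorff reports both the maximum and the 95th-percentile variant, since
  reports often do not state which is used.

## Known limitations

The displacement map is evaluated in a single frame (slowly-varying
assumption); very steep fields would need fixed-point inversion of the
forward map. Distortion is modelled as purely 1D along the readout axis —
phase-encode (EPI-type) distortion and through-plane effects are out of
scope. The dose model has no tissue heterogeneity or collimator physics.
The predictor is trained and evaluated on phantoms from the same generator;
its desk-scale accuracy says nothing about transfer to real scans.
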