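---
title: "Synthesizing double inversion recovery MRI: models, choices and limits"
author: "dirsynth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing double inversion recovery MRI: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Double inversion recovery (DIR) nulls the signal of white matter and
cerebrospinal fluid with two inversion pulses, leaving a grey-matter image
on which cortical multiple-sclerosis lesions — nearly invisible on T1, T2
or FLAIR — stand out as hyperintensities. DIR is slow to acquire and
absent from most routine protocols. `dirsynth` implements the alternative:
*synthesize* the DIR contrast from sequences every protocol already
contains (T1-weighted, proton-density-weighted, T2-weighted), using a 3D
conditional adversarial network, and *quantify* whether lesions read from
the synthetic image agree with those read from an acquired one.

Because clinical MRI cannot ship with a package, every stage runs against
a physics-based phantom whose ground truth is known exactly. The phantom
is first-class, tested code, not a fixture.

## Signal model

Each tissue is a point in (T1, T2, PD) space. Under mono-exponential
relaxation the simulated steady-state magnitudes are

* spin echo: `PD * (1 - exp(-TR/T1)) * exp(-TE/T2)`
* inversion recovery: `PD * |1 - 2 exp(-TI/T1) + exp(-TR/T1)| * exp(-TE/T2)`
* double inversion recovery:
  `PD * |Mz/M0| * exp(-TE/T2)` with
  `Mz/M0 = 1 - 2 exp(-TI2/T1) + 2 exp(-(TI1+TI2)/T1) - exp(-TR/T1)`,

with the convention that the first inversion plays at t = 0, the second at
t = TI1, and excitation at t = TI1 + TI2. `solveNullingTimes()` finds the
delay pair that nulls two T1 species simultaneously (damped Newton on the
2×2 system, grid-scanned start, residual < 1e-8).

**Tissue parameters.** 1.5 T literature-typical values: WM T1/T2 = 600/80,
GM 950/100, CSF 4000/2000, lesion 1100/120 ms; proton densities 0.7, 0.85,
1.0, 0.9. Lesions get prolonged relaxation and elevated PD relative to
grey matter, which is what makes them DIR-hyperintense. All values are
configurable; none are fitted.

**DIR timing.** The clinical acquisition string quotes TR/TE = 6500/355 ms
and two inversion delays printed as "350/2350". Under the stated pulse
convention, taking TI1 = 350 and TI2 = 2350 leaves CSF at ~59% of its
equilibrium magnetization — no suppression, which contradicts the entire
purpose of the sequence. The exact WM/CSF nulling solution at TR = 6500 is
(TI1, TI2) ≈ (2349, 404) ms — numerically the printed pair read in the
opposite order, within rounding of the second delay. The package therefore
defaults the phantom's DIR target to the solver's exact nulling delays
(preserving the defining suppression property) and leaves the printed
pairing available through `SequenceParams`. The pairing convention is an
acquisition-console detail with no bearing on the learning task, which
only needs a well-defined target contrast.

## The phantom generator

`makeTissuePhantom()` builds a deformed concentric anatomy — background ⊃
CSF layer ⊃ grey-matter ribbon ⊃ white-matter core — by thresholding a
normalized ellipsoidal radius modulated with a few random low-order
angular harmonics (amplitudes 2–6%), so each seed yields a distinct but
reproducible shape. Normalized radius bands 0.75 / 0.90 / 1.00 separate
WM, GM and CSF; with the default 32³–64³ extents this puts the ribbon at
roughly 2–4 mm thickness, the order of real cortical thickness.

Lesions are spheres placed relative to the ribbon according to their
type: mid-ribbon (intracortical), centred in WM with the sphere touching
the ribbon (juxtacortical), or centred on the WM/GM interface (mixed). A
requested intracortical lesion whose radius exceeds the local ribbon
thickness is an unsatisfiable placement and raises an error. Lobes are
assigned by a fixed angular partition of the axial plane into four
sectors — a deliberate stand-in for an atlas parcellation, since the
downstream tabulations only need consistent labels.

Noise is additive Gaussian, scaled as a fraction of the grey-matter
signal. Rician magnitude bias, B0/B1 inhomogeneity, partial-volume mixing
and k-space artifacts are deliberately out of scope: the downstream
network needs correct contrast *ordering* and geometry, not scanner
fidelity, and every simplification here is one the evaluation statistics
are insensitive to.

## Preprocessing

Volumes are z-scored with statistics computed **inside the brain mask**
(air would otherwise dominate the mean and variance — the source protocol
does not state which convention was used; the masked one is the only one
that keeps brain tissue within the clipping range), divided by four, and
clipped to [-1, 1]. Resampling under a given rigid/affine transform uses
cubic spline interpolation for intensities (an interpolating
cubic-convolution kernel: identity transforms reproduce inputs exactly)
and nearest-neighbour for masks. Registration *estimation* is out of
scope; transforms arrive from outside as FLIRT-style 4×4 text matrices,
and phantom pipelines use the identity.

## Patch sampling and augmentation

Training patches are cubes whose centre voxel lies in the brain mask,
drawn uniformly with replacement; the per-epoch sample count is
`floor(total brain voxels / patch_edge^3) * 8` pooled over training
subjects (with a floor of one batch so toy volumes still train). The
augmentation chain, per patch:

1. mirroring per axis, p = 0.5 each (predictors and target);
2. with p = 0.5, one combined rotation (per-axis angles U[-90°, 90°]) and
   scaling (per-axis factors U[0.8, 1.2]) resample, cubic interpolation,
   re-clipped (predictors and target);
3. predictor-only, p = 0.5: per-channel gamma on intensities remapped to
   [0, 1] (gamma on signed values is undefined), exponent U[0.8, 1.5];
4. predictor-only, each with p = 0.3 **independently** (the source's list
   formatting is ambiguous between exclusive and independent triggering;
   independent is the less restrictive reading and contains the exclusive
   one as a special case): additive Gaussian noise (SD 0.05), Gaussian
   blur with one sigma U[0.2, 1.5] shared across channels, and zeroing of
   one random channel.

After gamma/noise/blur the predictor channels are re-standardized
(z-scored over the patch, divided by four, clipped), since those
operations shift the distribution the network expects; the target patch
is geometrically transformed but never intensity-augmented, and it is
treated as an intensity image (cubic interpolation), not a mask. The
channel-zeroing convention doubles as the mechanism by which a trained
model tolerates a missing input channel at inference time.

## The adversarial translator

The generator is a U-shaped fully convolutional 3D network: encoder
levels halve the spatial extent (stride-2 convolution) and double the
filter count from `baseFilters`; the decoder mirrors it with
nearest-neighbour upsampling + convolution (transposed convolution would
invite checkerboard artifacts) and concatenates the same-resolution
encoder activation before a second convolution. Every convolution is
followed by instance normalization and leaky ReLU (slope 0.2); a final
convolution with tanh produces one channel in [-1, 1] at the input
resolution. The discriminator is a PatchGAN: the candidate DIR volume is
channel-concatenated with the predictors, reduced by stride-2
convolutions (kernel 4), and a one-strided sigmoid convolution yields a
map of validity scores, each judging one limited receptive field (46
input voxels across for the default 3-stage stack).

Losses: the generator minimizes binary cross entropy of its scores
against ones plus λ times the mean absolute error to the reference
(λ = 100 — the conventional weighting for conditional translation, not
stated by the source protocol; configurable); the discriminator minimizes
the mean of its real-vs-ones and fake-vs-zeros cross entropies. One
discriminator step then one generator step per batch, Adam (lr 2e-4,
β₁ = 0.5, β₂ = 0.999 at clinical scale), batch size 2, no learning-rate
decay. Whole volumes are predicted by sliding-window inference with
uniform overlap averaging.

The networks are implemented natively: im2col-based 3D convolutions in
C++ (column-major, spatial-fastest layout so the unfolding is contiguous)
with hand-written backward passes, verified against finite differences in
the test suite. Discriminator depth/filters are not specified by the
source description beyond the figure; 3 stages at base 32 (scaled
profiles: 2 at base 8) give a mid-sized receptive field.

## Problem sizes

The clinical-scale configuration (128³ patches, depth 5, base 32, 350
epochs) is the documented default but impractical without a GPU. The
package's own accuracy checks run a scaled profile chosen once: 32³
noiseless phantoms, depth 3, base 8, 16³ patches, 200 epochs, lr 1e-3,
one training and one held-out subject, augmentation off (the mapping to
be learned is a noiseless voxelwise function; augmentation models
scanner variability that the scaled phantoms do not contain). Under this
profile the held-out voxelwise correlation between predicted and analytic
DIR inside the brain mask reliably exceeds 0.9 and planted lesions remain
hyperintense relative to grey matter; the tests run three seeds and
require a majority. What this shows: the full pipeline — sampling,
augmentation plumbing, losses, backpropagation, optimization, stitching —
can learn a known cross-contrast mapping end to end. What it does not
show: performance on real, noisy, misregistered, pathology-bearing data.

## Lesion-level evaluation

`detectCandidates()` is the automated stand-in for a human rater: voxels
exceeding mean + z·SD of normal-appearing grey matter intensity form
26-connected components; components neither overlapping nor adjacent
(1-voxel dilation) to the GM mask are discarded, as are components whose
largest axial cross-section is under 3 mm² — the operational minimum for
calling a cortical lesion. Area is measured in-plane (largest axial
cross-section), consistent with 2D visual scoring.

Matching between the artificial-DIR and conventional-DIR detections of a
subject is greedy one-to-one on ascending centroid distance with a 5 mm
radius (the source protocol matched "location" visually; a radius is the
minimal formalization). Greedy matching can differ from maximum-cardinality
assignment when several lesions crowd within one radius; the oracle tests
therefore compare against exhaustive assignment in the separated regime
where the criterion is well defined, plus a fixed ambiguous instance.
Precision (TP/(TP+FP)) and recall (TP/(TP+FN)) are reported per subject,
pooled over summed counts, and as mean ± SD; zero-denominator subjects
are excluded from means with a note rather than scored 0.

Agreement in per-subject lesion counts uses the single-measure
absolute-agreement intraclass correlation from the two-way ANOVA
decomposition,

ICC = (MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE)),

with the F-distribution confidence bounds (Satterthwaite-approximated
denominator degrees of freedom) — the standard construction for a
two-way mixed, absolute-agreement design with fixed methods. Lobe/type
contingency tables count matched pairs (inheriting lobe and type from the
conventional-DIR member — the reference reading — where the two disagree),
artificial-only and conventional-only detections, with column percentages
at one decimal.

## Numerical choices and degenerate inputs

* Nulling solver: tolerance 1e-8 on both residuals; errors if no root
  lies in (0, TR). Equal T1 values are rejected (singular system).
* Normalization errors on zero variance inside the mask.
* ICC requires n ≥ 3 subjects and errors on zero total variance; a
  duplicated column returns exactly 1 with a degenerate interval. The
  point estimate can undershoot −1/(k−1) slightly in finite samples and
  is reported unclamped; F quantile df are capped at 1e6.
* BCE probabilities are clamped to [1e-7, 1 − 1e-7]; training aborts with
  a diagnostic on non-finite losses.
* Patch extraction zero-pads beyond the field of view; stitching trims
  padding after averaging.
* All randomness flows through explicit seeds; the RNG state of the
  calling session is always restored.

## Known limitations

Single-echo idealization (no echo-train blurring, no readout flip-angle
effects); Gaussian rather than Rician noise; angular-sector lobes; a
detector stand-in rather than expert raters — the package reproduces the
*arithmetic* of the reading study (counts in, statistics out), not the
human scoring procedure itself. The clinical-scale training claim (that
the synthesis quality suffices for prospective human reading) is not
testable at desk scale and is not asserted by any test.
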