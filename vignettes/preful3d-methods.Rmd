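---
title: "Phase-resolved functional lung MRI from 3D radial UTE acquisitions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{preful3d methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`preful3d` implements a complete free-breathing ventilation-mapping chain
for lung MRI with a center-out 3D golden-means radial (koosh-ball) UTE
acquisition:

1. **Self-gating**: the k-space centre (DC) signal of every radial spoke
   tracks total image signal, which is modulated by respiration because
   parenchymal proton density falls as the lung inflates.  The DC waveform
   is smoothed (Savitzky–Golay), de-drifted by block-wise min–max
   rescaling, and spokes are sorted into respiratory states.
2. **Reconstruction**: each state is reconstructed by regularized
   iterative SENSE on a gridding NUFFT, with 3D total-variation and
   Symlet-4 wavelet penalties.
3. **Spatial processing**: states are registered to the mid-respiration
   state, the thoracic cavity is segmented by seeded region growing, and a
   3D guided filter is applied.
4. **PREFUL analysis**: 15 equidistant respiratory phases are interpolated
   voxel-wise by non-parametric regression; regional ventilation is
   `RVent = (S_ex - S_in)/S_ex`; the ventilation defect percentage (VDP)
   is the lowest k-means cluster of the RVent distribution.
5. **Comparison machinery**: threshold VDP for ventilation-weighted
   (hyperpolarized-gas style) volumes, carina-based eight-region
   partition, Dice overlap with slab matching, Bland–Altman, one-way
   ANOVA with Bonferroni correction, and a mixed-effects correlation with
   Nakagawa–Schielzeth marginal R² and Satterthwaite p-values.

Because no clinical raw data are available, the package carries a
ventilating digital thorax phantom whose ground truth (ventilation map,
lung mask, defect mask, true VDP, per-spoke respiratory phase) supports
end-to-end recovery tests.

## The phantom as a stated world

The phantom is an ellipsoidal body containing two ellipsoidal lungs.  At
respiratory amplitude `b` (0 = end-expiration, 1 = end-inspiration) the
parenchymal intensity is

    S(x, b) = rho * (1 - alpha * v(x) * b)

with parenchyma baseline `rho = 0.5` (body 1.0), ventilation amplitude
`v(x)` equal to 1 in healthy lung and scaled down inside spherical
defects, and tidal density change `alpha = 0.3`.  The source literature
does not state the tidal signal-change fraction; `alpha = 0.3` is a
phantom choice consistent with reported UTE signal modulation between
expiration and inspiration.  The frame is then warped by a smooth
superior-inferior displacement (raised-cosine profile peaking at the
diaphragm dome, default maximum 5% of the grid, ~3 voxels at 64³).

Fixed-once choices, with reasons:

- **Breathing**: raised-cosine cycle, period 4 s, inspiration fraction
  0.4 — a typical relaxed adult/adolescent pattern.
- **Drift**: multiplicative receiver-gain drift
  `g(t) = 1 + 0.2 sin(2 pi t / 600 s)`.  The amplitude 0.2 is prescribed;
  the time constant is not.  Receiver-chain and gradient-heating drifts
  evolve over minutes, so 600 s is the physical choice; an earlier draft
  used 100 s, which makes the *within-block* gain change comparable to the
  tidal DC modulation — a regime no receiver exhibits and one that the
  block min–max rescaling (which can only normalize *between* blocks)
  cannot repair even in principle.  At desk scale the 600 s drift still
  sweeps ~8% gain over the scan: without rescaling the waveform-truth
  correlation collapses to ~0.3, so the de-drifting stage is genuinely
  exercised.
- **Noise**: "SNR 20" is interpreted on the image-equivalent scale:
  complex k-space noise with SD `noise_sigma * peak_intensity *
  sqrt(N_voxels)`, the standard recipe that makes a fully-sampled
  Cartesian reconstruction have voxel noise SD `noise_sigma * peak`.
- **Forward model**: the breathing amplitude is quantized to 64 levels
  and one 3D frame is rendered per level (not per spoke); with a 4 s
  period and 1.9 ms TR the amplitude changes by well under one
  quantization step between consecutive spokes, so the approximation is
  below the noise floor.
- **Coil maps**: smooth complex Gaussians centred on points around the
  torso, with mild linear phase ramps; default 4 coils.

What the phantom does **not** emulate: T2*/off-resonance decay, cardiac
signal, gradient-nonlinearity distortion, anatomical texture, and
non-rigid three-dimensional breathing deformation beyond the SI
displacement.  A green end-to-end test therefore establishes that the
pipeline recovers ventilation defects under idealized contrast and motion,
not that it is robust to every in-vivo confounder.

## Numerical choices

**NUFFT.** Kaiser–Bessel gridding with oversampling 1.25 and kernel width
5 (Beatty beta), deapodized with the kernel's analytic Fourier transform.
Forward accuracy vs. a direct non-uniform DFT is ~2e-3 relative; spread
and interpolation share one lookup table so the adjoint pair passes the
dot-product test at ~1e-15.  The iterative reconstruction uses width 4
(~2x faster, ~8e-3 accuracy) — deliberately a *different* discretization
from the simulator's, so simulation and inversion do not share one
operator (inverse crime).

**Density compensation** is the analytic 3D radial rule `w ~ r² dr`,
normalized per spoke.  The k-space centre sample receives weight 0 (the
`r² dr` shell volume vanishes); this follows the closed-form rule rather
than the strict-positivity wording of the interface contract.

**Solver.** With both penalties zero the normal equations are solved by
plain conjugate gradients.  Otherwise the objective

    sum_c ||W^1/2 (F S_c x - y_c)||² + l_tv TV_eps(x) + l_wav ||Psi x||_1

is minimized by monotone proximal gradient: the data term and a smoothed
isotropic TV (eps = 1e-3) are handled by gradient steps with backtracking
line search, the orthogonal-wavelet l1 term by exact soft-thresholding.
This deviates from an alternating CG/proximal scheme on purpose: proximal
gradient with backtracking guarantees a monotone composite objective,
which the package treats as a hard invariant (five consecutive increases
abort the solve).  The step size is carried over between states, since
consecutive respiratory states pose nearly identical problems.

**Lambda normalization.** Printed penalty weights (`lambda = 0.01`) are
interpreted as the ratio of each penalty to the *initial* data energy at
the warm-started iterate, so `lambda_tv = 0.01` means "the TV term starts
at 1% of the data term" regardless of grid size, sample count, or
intensity scale.  Without such a convention the same printed lambda can
be anywhere between *no-op* and *dominant* depending on how the operator
and data happen to be scaled.

**Drift correction of the data.** Block-wise rescaling fixes the gating
waveform but not the k-space data: amplitude binning mixes spokes from
all times into one state, so a 20% receiver drift leaves the state's
spokes mutually inconsistent by up to ~15%, which surfaces as boundary
artifacts in the state images and ultimately as spurious low-RVent
voxels.  `estimate_drift_gain()` estimates the slow gain as the per-block
mid-envelope `(min+max)/2` of the smoothed DC signal (first-order removal
of the breathing oscillation), interpolated across blocks and normalized
to mean 1; `reconstruct_states(..., drift_gain =)` divides the spoke data
by it.  This DC-navigator amplitude correction is standard practice in
self-gated radial imaging.

**Registration** is a multi-resolution free-form deformation: a
displacement field on a coarse control grid (spacing 12 voxels),
trilinearly interpolated, optimized by backtracking gradient descent on
the SSD with an analytic gradient, two resolution levels.  "Mid
respiration" is the state with amplitude closest to 0.5, not the middle
index, which is robust to uneven state occupancy.  The contract is the
recovery property (a known shift is recovered; SSD never increases, else
identity fallback), not a particular parameterization.

**Segmentation** is 6-connected region growing with a running-mean
acceptance rule, `|I - mean(region)| <= tolerance * robust_range`,
closing (radius 1) and hole filling, with leak rejection if the region
touches more than 10% of the image border.  `"auto"` seeding takes the
two largest dark components inside the hole-filled bright body support —
restricting to the body support is what prevents background air (equally
dark) from being seeded.

**Guided-filter guide.** The pipeline filters each registered state with
the *temporal mean* of all states as the guidance image.  Anatomy is
identical across states while each state's undersampling streaks come
from a different spoke subset, so structure present in the guide
(anatomy) is transferred and structure absent from it (streaks, noise) is
smoothed away.  The regularization `eps = 0.01` sits well below the
squared lung-body contrast (~0.2), so tissue edges are preserved.  Self-
guided filtering remains available through `guided_filter3d()` directly.

**Phase interpolation** uses *local-linear* (not Nadaraya–Watson) kernel
regression: local-linear weights reproduce exactly-linear signals for any
design, which the package treats as a contract.  Bandwidth defaults to
1.5x the output phase spacing.

**RVent and VDP.** End-expiration is the phase-grid end with the larger
mean lung signal.  The default convention is the fractional-ventilation
form `(S_ex - S_in)/S_ex`; the inspiration-denominator variant is a flag,
since the source defers the formula to prior literature.  k-means VDP uses
k = 4, lowest cluster as defect (the convention of the k-means VDP
literature), Lloyd's algorithm with 50 restarts under a fixed seed.
Negative RVent values are clipped to zero before clustering (flag
`clip_negative`): negative fractional ventilation is unphysical
measurement noise, and a small far-negative outlier group would otherwise
capture the "lowest cluster" slot and hide the true defect — clipping maps
those voxels onto the defect side, which is what they represent
physically.  The 2D mode pools coronal-slice values (numerically equal to
3D on identical input; a per-slice flag exists).

**Threshold VDP** uses strict `<` at `frac * mean` (voxels exactly at the
threshold are healthy) for bit-exact reproducibility, and is
scale-invariant by construction.

**Mixed model.** `lmm_correlation()` fits the random-intercept model by
direct dense REML (profiled over the residual variance), which is
practical at the cohort sizes involved and is verified against `lme4` in
the test suite.  Satterthwaite degrees of freedom use the delta method on
the numerically differentiated REML information.  With one observation
per subject the variance split is unidentifiable; the fit is taken at the
boundary (`sigma²_u = 0`), reducing to ordinary regression with `n - 2`
degrees of freedom.  Marginal R² is the Nakagawa–Schielzeth form
`var(b1 x) / (var(b1 x) + sigma²_u + sigma²_e)`.

**Eight-region partition.** Left/right uses the sagittal plane through
the carina's x-coordinate (under the axis convention x: right to left,
`x < carina` is the right lung); superior/inferior the transverse plane
through its z; anterior/posterior the coronal plane through its y — the
stated "sagittal position separating anterior and posterior" is read as
the plane orthogonal to the anterior-posterior axis.  Volume-weighted
regional VDPs recombine exactly to the global VDP, which is a tested
invariant.

**Dice conventions.** Both-empty masks give DSC 1 with a flag; pooled
boolean maps re-binarize at >= 0.5 -> defect.  These conventions are
documented because they affect reproducibility of reported DSC medians on
near-empty defect masks.

## Scale, runtime, and what the tests establish

Desk-scale defaults (64³ grid, 20 000 spokes, 64-sample readout, 10
states) stand in for the full acquisition scale (2 mm³ over a 500 mm
field of view, 280 000 spokes, 30 states), which is config-reachable
(`scale = "full"`) but not exercised by the tests.  The end-to-end
acceptance test runs the desk scale with 2 receive coils (the phantom
default is 4) purely as a runtime measure; coil count is not part of the
stated recovery conditions.  At desk resolution the lung boundary shell
(1-2 voxels) is ~30% of the lung volume, so partial-volume voxels — whose
fractional ventilation is genuinely diluted by body signal — dominate the
behaviour of the lowest k-means cluster in a way the full-resolution
setting would not; the recovery test's tolerance (±3 percentage points)
absorbs the measured ideal-reconstruction floor (~+0.3 pp) but is tight
against reconstruction-noise-driven misclassification of shell voxels.

## Known limitations

- The registration family is a linear-interpolated FFD, not the cited
  toolbox's polynomial model; only the recovery contract is promised.
- The polynomial bias-field correction is a surrogate for dedicated
  tools, suitable for the smooth synthetic bias fields it is tested on.
- Perfusion-weighted analysis, flow-volume loops, trajectory-error
  correction and DICOM ingestion are out of scope.
- `vdp_kmeans` determinism is guaranteed for a fixed seed and identical
  input; across BLAS builds the restart optimization could in principle
  select a different local optimum on adversarial inputs.
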