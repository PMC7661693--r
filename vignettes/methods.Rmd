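---
title: "Subtractionless Dixon MR angiography: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtractionless Dixon MR angiography: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
signal model, the reconstruction and analysis algorithms, the parameters
that matter, and the design decisions taken where a published description
leaves the details open. Everything quantitative stated here is computed by
the package's test suite or by `scripts/acceptance.R`; the vignette itself
states no empirical result beyond those.

## Signal model and SNR theory

A dual-gradient-echo acquisition samples, per voxel, the complex signal

$$S_n = \bigl(W + F\,c(TE_n)\bigr)\, e^{i 2\pi \psi TE_n} + \varepsilon_n ,
\qquad n = 1, 2,$$

where $W, F \ge 0$ are water and fat magnitudes, $\psi$ (Hz) the smooth
off-resonance field, $\varepsilon_n$ i.i.d. complex Gaussian noise with
per-channel SD $\sigma$, and

$$c(TE) = \sum_m a_m e^{i 2\pi \Delta f_m TE}$$

the fat spectral phasor ($\sum_m a_m = 1$). The default model places all
fat signal at $\Delta f_F = -421.5$ Hz, the dominant fat–water offset at
3 T; `fat_model_multi_peak()` provides a six-peak triglyceride stand-in for
exercising the multi-peak code path (its peak table is an implementation
choice, not a measured spectrum).

Two background-suppression routes are compared:

* **Subtraction**: $|S^{\text{post}}_1| - |S^{\text{pre}}_1|$. Signals
  subtract; the uncorrelated noise adds in quadrature, so the noise SD
  grows by $\sqrt2$ while the vascular signal (pre-contrast lumen signal
  is below 10% of post-contrast and treated as negligible) does not.
* **Water–fat separation** (mDixon): the post-contrast dual-echo data are
  solved for $W$; the water image is inherently fat-suppressed. With the
  field phasor known, $W$ is a linear combination of the two echoes and
  its noise SD is $\sigma / \sqrt{1 - \cos(2\pi\,\Delta TE\,\Delta f_F)}$.

Hence `separation_gain()` $= \sqrt{1 - \cos(2\pi \Delta TE \Delta f_F)}$
(at most $\sqrt2$, attained at $\Delta TE = 1/(2|\Delta f_F|)$,
`optimal_echo_spacing()`), and `total_gain()` multiplies in the $\sqrt2$
from omitting the subtraction, for a maximum of exactly 2. The sign of
$\Delta f_F$ is irrelevant inside the even cosine; the magnitude is used.

## The synthetic phantom

No clinical data ship with the package; every downstream stage is
exercised on a synthetic three-station peripheral exam with known ground
truth. Per station (`default_phantom_spec()`):

* **Grid**: 144 × 64 × 86 voxels at 3 × 3 × 5 mm — a 432 × 192 × 430 mm
  field of view, 430 mm foot–head as in a stepping-table station. The
  in-plane resolution is deliberately coarser than a clinical protocol
  (1–1.3 mm) to keep simulation and reconstruction fast; vessel radii are
  chosen generously (3.5–12 mm) so lumina stay resolvable.
* **Vessel tree**: 23 named segments over the three stations (7/8/8):
  infrarenal aorta and iliacs; common/deep/superficial femoral and
  popliteal; tibiofibular trunk, tibial and peroneal arteries. Tubes are
  rasterized by the point-in-cylinder rule on voxel centres; a stenosis
  fraction shrinks the radius over the middle third of a segment (the
  right superficial femoral artery carries a 50% stenosis by default);
  occluded segments contribute no lumen.
* **Tissue**: an elliptical body cross-section with a 12 mm subcutaneous
  shell at fat fraction 0.9 and an interior at 0.2, total tissue density
  1 (arbitrary units). Lumen voxels are pure water at density 1.
* **Contrast**: post-contrast lumen water is scaled by
  `enhancement_factor = 4`; pre-contrast lumen signal is 5% of
  post-contrast (first-pass saturation bounds it below 10%; 5% is the
  package's choice of a typical value).
* **Field map**: a smooth separable cosine bump, amplitude 30 Hz, spatial
  scale 150 mm — moderate 3 T shim inhomogeneity.
* **Noise**: complex Gaussian, per-channel SD 0.1, giving a post-contrast
  lumen SNR of ~40, typical of first-pass CE-MRA, and a regime in which
  the reconstruction stays free of water–fat swap artifacts (at SD 0.15
  the fat shell begins to swap). Noise-only acquisitions
  (`simulate_noise_only()`) emulate scans with RF excitation disabled.

What the phantom does **not** emulate: parallel-imaging g-factor noise
structure (noise is spatially uniform; an option the theory also assumes),
partial-volume effects at lumen boundaries (masks are binary), motion and
misregistration (the pre/post pair is perfectly registered), venous or
background enhancement, and k-space effects (SENSE, partial Fourier).
Passing tests therefore demonstrate algorithmic correctness and
theory-consistency, not clinical performance: in particular the perfectly
registered subtraction background is *easier* than in vivo, which biases
the VBC comparison against the water image, and measured VBC magnitudes
on the phantom are not comparable to patient values.

All randomness flows from one root seed through named substreams
(per subject, station, contrast), so any stage can be reproduced in
isolation and simulators do not disturb the caller's RNG state.

## Two-point Dixon reconstruction

`separate_water_fat()` composes two stages.

**Per-voxel candidates** (`solve_two_point()`). Writing
$S_1 = (W + c_1 F)q_1$, $S_2 = (W + c_2 F)q_1 p$ with unit phasors $q_1$
(initial phase) and $p$ (between-echo field phasor), eliminating the
phases leaves the homogeneous quadratic
$\alpha W^2 + \beta WF + \gamma F^2 = 0$ in the candidate direction, with
$\alpha = m_2^2 - m_1^2$, $\beta = 2(m_2^2 \Re c_1 - m_1^2 \Re c_2)$,
$\gamma = m_2^2|c_1|^2 - m_1^2|c_2|^2$ and $m_n = |S_n|$. Its two roots
are the water/fat swap ambiguity. Numerical care: each root keeps the
better-conditioned of its two homogeneous representations; a negative
discriminant (possible under noise) is clamped to zero; directions leaving
the nonnegative quadrant are projected onto the nearer of the pure-water /
pure-fat axes; the least-squares scale and a magnitude-space residual are
attached to each candidate. Zero-signal voxels return $(0,0)$ with an
undefined phasor. An echo pair with $|c_1 - c_2| < 10^{-3}$ cannot
separate water from fat and is rejected with the echo times named.

**Swap resolution** (`resolve_ambiguity()`). The correct candidate is the
one whose between-echo phasor follows the smooth field. The
highest-magnitude voxel above the signal floor seeds the first region with
its lower-residual candidate; residuals are compared with a
magnitude-relative tolerance ($10^{-6} m$) because both candidates
usually fit the magnitudes exactly, and ties prefer the water-dominant
candidate (in CE-MRA the brightest structure is the enhanced lumen). The
region then grows through its 6-connected frontier in descending
magnitude order (max-heap; ties by linear index), each voxel choosing the
candidate closest to the magnitude-weighted mean phasor of its resolved
26-neighbourhood. Three robustness rules matter at realistic noise:

* voxels whose two candidate phasors nearly coincide (complex distance
  ≤ 0.05 — noise-degenerate double roots, whose collapsed phasor lies
  halfway between the hypotheses) are resolved but never contribute to
  neighbour means;
* a voxel reached with no informative resolved neighbour is deferred and
  retried after the region has grown, rather than guessing;
* disconnected regions seed independently.

The resolved phasor field is optionally box-smoothed (`field_smooth`,
default radius 1 voxel, weights = magnitude × resolved); both echoes are
then demodulated and a per-voxel 2 × 2 complex linear solve yields the
final magnitudes $W = |W_c|$, $F = |F_c|$. With `field_smooth = 0` the
exact per-voxel phasor is used, which makes noiseless recovery exact to
rounding; with smoothing the noisy water image attains the closed-form
noise propagation $\sigma/\sqrt{1-\cos(\cdot)}$.

**Signal floor.** Voxels with mean echo magnitude below
$3\hat\sigma$ ($\hat\sigma$ from the lower quartile of the first-echo
magnitude under a Rayleigh background assumption, or supplied) are
excluded from region growing; they keep an identity demodulation and still
receive the linear-solve magnitudes. Backgrounds therefore retain their
noise texture — zeroing them would fabricate perfect background
suppression and make both the VBC background SD and the noise-only SD
measurements degenerate.

## Subtraction, MIP, stitching

`subtract()` is voxelwise magnitude subtraction of the first echoes
(magnitude, not complex: complex subtraction lets the phases interact
unfavourably). Negative residuals are clipped to zero for rendering
(`clip = TRUE`, the default) because a MIP of signed residuals surfaces
noise; *quantitative* uses take `clip = FALSE`, since clipping a zero-mean
background halves its apparent SD and distorts every noise statistic.
`mip_coronal()` projects along the anterior–posterior axis;
`stitch()` places station MIPs at their table offsets and combines
overlaps by per-pixel maximum (consistent with MIP semantics and
reproducible; no feathering). Under the default layout — three 430 mm
stations with 40 mm overlaps — the panorama spans 1210 mm foot–head. Gaps
between stations warn and stay zero.

## Semi-automated VBC analysis

Per cylindrical ROI (voxel membership by the point-in-cylinder rule on
voxel centres, axis defaulting to the axial slice normal):

1. **Local maxima**: up to `k = 10` strict-or-plateau maxima in the
   26-neighbourhood, *ROI-restricted* — a cylinder cuts through its
   vessel, and comparing against brighter lumen voxels just outside the
   caps would delete the lumen maxima in short or stenosed ROIs. Plateaus
   collapse to the centroid-nearest member; ordering is by descending
   intensity with linear-index ties; a constant ROI is flagged degenerate.
2. **Seed**: the innermost maximum (Euclidean distance to the ROI
   isocenter; ties to higher intensity, then lower index), restricted to
   maxima within $\theta$ of the brightest one. The unqualified innermost
   rule presumes the innermost maximum is vessel; background noise also
   produces maxima, and on a stenotic throat one can sit nearer the
   isocenter than the surviving lumen maxima — seeding there floods the
   whole background.
3. **Lumen**: 26-connected flood fill from the seed over ROI voxels with
   intensity $\ge \theta\, I(\text{seed})$, $\theta = 0.5$ by default
   (configurable; the inclusion rule is the package's explicit stand-in
   for an unpublished criterion).
4. **Background**: ROI minus lumen; every other maximum that is itself
   hyperintense ($\ge \theta I(\text{seed})$) seeds its own fill (same
   rule, applied to that maximum) and the region — a branch or other
   bright structure — moves to the discarded mask; any remaining voxel
   $\ge \theta I(\text{seed})$ is discarded too. Sub-threshold maxima are
   ordinary background texture and stay. An empty background is an error
   naming the ROI.
5. **Statistic**: `VBC = (mean_vessel − mean_background) / SD_background`
   with sample ($n-1$) SD; invariant under positive affine intensity
   maps. The segmentation derived on the water image is applied unchanged
   to the subtraction image (`transfer_segmentation()`).

`run_study()` evaluates VBC on the *signed* subtraction volume while the
clipped volume feeds the MIPs, for the clipping reason above; on a
perfectly registered phantom the subtraction background is exactly
zero-mean, the worst case for clipping bias.

## Noise-only SNR measurement

`empirical_gain()` mirrors the volunteer experiment: with RF excitation
disabled both reconstructions see pure noise, and the SNR gain equals the
ratio of noise SDs measured in the same ROIs — per ROI the sample SD of
each volume, averaged per station and overall, gain = mean SD(subtraction)
/ mean SD(water). The subtraction path uses the unclipped signed
magnitude difference of two independent noise acquisitions; the water path
is the magnitude of the Dixon linear solve (all noise voxels sit below the
signal floor). Both magnitudes carry the same Rayleigh-type shape factor,
which cancels in the ratio, so the measured gain converges to
`total_gain()` in expectation; the suite verifies agreement within 5% at
≥ 10⁵ voxels.

## Reader agreement

`quadratic_weighted_kappa()` implements
$\kappa = 1 - \sum w_{ij} O_{ij} / \sum w_{ij} E_{ij}$ on the 0–3 quality
scale with $w_{ij} = (i-j)^2/(k-1)^2$, $O$ the joint proportion matrix and
$E$ the product of marginals (proportions rather than counts; the value is
identical). When both readers are constant and identical the expected
weighted disagreement is zero and no plausible $\kappa$ exists: the result
is flagged degenerate with an `NA` estimate instead of a number. The
conventional verbal bands (≤ 0 poor … 0.81–1.00 excellent) are attached.
Routine significance tests (Shapiro–Wilk, t, Mann–Whitney) are left to
`stats`; `summarize_scores()` only wires the grouped mean ± SD reporting.

## Interfaces and problem sizes

The package is tidyverse-shaped: results are tibbles, study bundles have
`tidy()`/`glance()`, images have `autoplot()`. There is deliberately no
shell executable — users of an analysis package like this work in R, and
`pipeline_config()` + `run_study()` (YAML-serialisable phantom specs,
NIfTI/CSV/PNG/JSON outputs) are its entry points.

Default problem sizes were chosen once for the package's own test and
demonstration workloads: 793k-voxel stations for the study driver, a 64³
noiseless phantom for the recovery check, ≥ 10⁵ voxels for Monte-Carlo
noise checks, 100 fuzzed small phantoms for mask invariants, and a
10-subject run (690 ROIs per method) for the bookkeeping check.

## Known limitations

* The Dixon variant is a fixed, documented one (two echoes, optional
  box-smoothed field phasor); scanner products add proprietary field-map
  regularisation and multi-resolution growing, and three-plus-point
  variants, R2* estimation and k-space-domain processing are out of scope.
* Swap resolution is heuristic under heavy noise: at tissue SNR below ~7
  the fat shell begins to swap in patches.
* The VBC defaults ($\theta = 0.5$, `k = 10`, 26-connectivity) are
  explicit stand-ins for unpublished algorithmic details; conclusions
  drawn from the phantom comparison are directional, not quantitative.
* Cylinder ROIs assume the axial-reformat axis; oblique vessels get
  slightly conical effective ROIs.
* Inter-station registration and motion correction are not modelled or
  performed; misregistration is a property of real data the phantom
  intentionally lacks.
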