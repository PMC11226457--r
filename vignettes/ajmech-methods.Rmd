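---
title: "Models and methods behind ajmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ajmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ajmech)
```

ajmech implements the quantitative stack used to study how force is
transmitted across adherens junctions: axial nanometry of junctional
proteins, single-molecule mechanics of the vinculin/catenin link, FRAP
turnover, junction tension by laser ablation, and collective-migration
statistics. This vignette explains each model, the parameters that matter,
the design choices made where the procedure was genuinely open, and what
the synthetic-data generators do and do not emulate.

## SAIM axial nanometry

### Forward model

A fluorophore at height $h$ above the oxide surface of a silicon-mirror
substrate is excited by the interference of the direct and
mirror-reflected illumination. The per-angle excitation intensity is
modelled as

$$F_j = \left| 1 + r(\theta_j)\,e^{i\phi_j} \right|^2, \qquad
  \phi_j = \frac{4\pi n_m h \cos\theta_j}{\lambda},$$

with $r(\theta)$ the complex amplitude reflection coefficient of the
medium/oxide/silicon stack from single-film (Airy) interference of the two
interfaces. This is the minimal standing-wave model: emission-side
interference, dipole orientation and supercritical effects are ignored
(they modulate the amplitude smoothly and are largely absorbed by the
per-pixel scale $A$ and offset $B$).

Optical constants are not measurable from the image data, so defaults are
textbook values, all overridable: $n_m = 1.33$, $n_{ox} = 1.463$,
$n_{Si} = 4.37 - 0.08i$ at 488 nm (about $4.05 - 0.04i$ at 561 nm), oxide
thickness 500 nm. Polarization defaults to TE (s), the dominant component
of azimuthally scanned illumination; TM and TE/TM-average are available.
Sweep angles are propagation angles in the sample medium (conversion from
objective-side angles is upstream of this package). Because the absolute
optical phase depends on these conventions, absolute heights carry a
systematic offset of a few tenths of a nanometer that cannot be pinned
down without per-chip calibration; recovery of *simulated* heights, which
share the conventions, is exact.

### Per-pixel inversion

Measured intensities are fitted as $I_j \approx A\,F_j(h) + B$ by
least squares over $(h, A, B)$. The objective is highly multimodal in $h$
(the excitation is quasi-periodic in height), so the fit multi-starts from
a grid over $h \in [0, 200]$ nm every 10 nm — covering the 40–140 nm
display range of junctional proteins with margin — and keeps the restart
with the smallest residual sum of squares, ties broken toward the lowest
height. Each local refinement is a damped Gauss–Newton
(Levenberg–Marquardt) iteration with the analytic Jacobian; $h$ is kept in
bounds by clipping and negative amplitudes are clipped to zero and
flagged. Convergence is declared at a relative RSS decrease below
$10^{-12}$ or a cap of 60 iterations.

For whole-field fits, `fit_saim_stack()` first scores the restart grid for
all pixels at once — at fixed $h$ the model is linear in $(A, B)$, so the
best $(A, B)$ and RSS have closed forms — and then runs the LM refinement
per pixel from its winning restart. `fit_saim_pixel()` refines every
restart. The test suite checks both against an independent exhaustive grid
search (0.01 nm step, linear subproblem solved at every step).

ROIs are summarized by the median of the finite fitted pixel heights
(`z_center`), the even-count median being the mean of the two central
values. The median is insensitive to the occasional pixel that locks onto
a wrong interference branch.

## Worm-like-chain rupture steps

### Polymer model

Released polypeptide contour is treated as a worm-like chain with bending
persistence $L_p = 0.8$ nm, contour 0.38 nm per residue and
$k_BT = 4.28$ pN·nm (310 K). The Marko–Siggia interpolation

$$F(x) = \frac{k_BT}{L_p}\left[\frac{1}{4(1 - x/L)^2} - \frac{1}{4}
  + \frac{x}{L}\right]$$

is inverted numerically (monotone root-finding to $10^{-6}$ pN) rather
than using the high-force asymptote, because dissociation forces of
interest reach down to ~5–7 pN where the asymptote is poor.

### Construct accounting

The detector construct is avi–VBS–FH1–VD1–I27$_2$–spy with GGGSG linkers
between components. In the looped state force bypasses the FH1 spacer
through the VBS–VD1 complex. The released contour per scenario is:

* **unloop_only** — the 182-residue FH1 spacer plus 40 flexible residues
  (the two flanking GGGSG linkers and the ~30-residue VBS segment, which
  leaves the complex as disordered chain on dissociation);
* **unloop_partial_unfold / unloop_full_unfold** — additionally one or
  both VD1 subunits at 126 residues each (VD1 spans residues 1–252 and
  unfolds non-cooperatively in two helix-bundle subunits; the exact
  per-subunit residue count is construct-specific and is configuration,
  not a constant);
* **subunit_unfold** — one subunit alone, the ~30 nm step seen when no
  loop is formed.

Each release credits the WLC extension of its contour at the rupture force
minus a folded span of 4 nm (the extension the folded element already
contributed); releases are additive. With these defaults the unlooping
band runs from ~39 nm at 7 pN to ~54 nm at 16 pN, one-subunit unfolding
adds ~29 nm (staying under 90 nm at 16 pN) and complete unfolding exceeds
100 nm. Published accounts of the same construct give the unlooping band
as 40–50 nm in one place and 50–60 nm in another; the 40–50 nm reading is
adopted and the discrepancy is noted here rather than resolved.

```{r bands}
predicted_step("unloop_only", c(7, 16))
predicted_step(c("unloop_partial_unfold", "unloop_full_unfold"), 16)
```

### Step detection and classification

No step-detection algorithm is prescribed by the experimental description,
only the observable (stepwise bead-height changes on a 1 pN/s ramp sampled
at 10 ms). The detector is a two-sided sliding-window mean-difference
statistic: at each sample the means of the `window` (default 30) samples
before and after are compared; extrema exceeding both a minimum step
(10 nm) and `significance` (6) times the null SD of the statistic
(estimated robustly from first differences) are events, with neighboring
candidates within one window merged. Step sizes are measured by linear
fits on the flanking windows extrapolated to the change point — plain
window means would absorb ~0.1 nm of ramp-baseline drift into the step.

Classification follows the attribution rule: steps at or below 35 nm are
`below_threshold` (isolated subunit unfolding reaches similar sizes);
larger steps are assigned the scenario whose predicted band
(prediction ± 10 nm) contains them at the measured force, anything above
the full-unfold prediction is `unloop_full_unfold`, and band overlaps
resolve to the scenario with fewer released segments (parsimony). Force
uncertainty is reported as 20% of the measured force (bead-size and
attachment-geometry variation). DNA-handle elasticity, bead geometry and
titin I27 unfolding (a >60 pN phenomenon) are outside the model.

## FRAP

Double normalization corrects the bleached-ROI mean for acquisition
photobleaching and background,

$$I_{norm}(t) = \frac{Iref_{pre}}{Iref(t) - Iback(t)} \cdot
  \frac{Ifrap(t) - Iback(t)}{Ifrap_{pre}},$$

with the *pre* quantities averaged over all frames strictly before the
bleach (4 by default) after background subtraction; background may be a
constant or a per-frame series. Full-scale calibration then maps the
pre-bleach average to 1 and the bleach frame to 0. The recovery is fitted
by bounded nonlinear least squares as $I(t) = p(1 - e^{-kt})$ with $t$
from the bleach frame; initialization takes $p_0$ from the last-quartile
mean and $k_0 = \ln 2 / t_{1/2}$ from the time to half of $p_0$; bounds
are $p \in [0, 1.5]$ (values above 1 are flagged) and $k \in (0, 10]$
s$^{-1}$ (rates at a bound are flagged). Because the full-scale curve of a
fully mobile pool saturates at 1, the fitted plateau $p$ *is* the mobile
fraction relative to total; the half-life is $\ln 2 / k$ exactly.

Whether recovery fitting should target the full-scale curve or the
merely double-normalized one is ambiguous in common practice; the
full-scale curve is the default here (it makes $p$ the mobile fraction
directly) and the alternative amounts to rescaling before the fit.

## Ablation recoil

Edge tracks are summarized by the inter-edge Euclidean distance per frame;
no arc-length along the junction is attempted. The initial recoil rate is
the one-sided secant over the first 2 s after the cut (one frame interval
at the standard 2-s acquisition), not a multi-frame linear fit — matching
the stated measurement window. Whether one sums the two edge speeds or
differentiates the inter-edge distance is equivalent for symmetric recoil;
the distance rate is used. Comparisons across conditions use one-way ANOVA
with Sidak-corrected pairwise tests. Kelvin–Voigt viscoelastic fitting of
the full relaxation is deliberately out of scope.

## Migration angular statistics

Vectors slower than 10 µm/h are removed as motion noise, the threshold
read strictly (speeds exactly at 10 are retained). Directions
($\mathrm{atan2}(v, u)$, 0° = outward wound normal, which callers align
with +x) are pooled across frames and positions and binned into twelve 30°
bins. By default bin edges sit at −15°, 15°, 45°, … so that 0° is a bin
center — directional flows peak perpendicular to the wound edge and an
edge at 0° would split the modal bin — with edge-aligned bins available by
switch. Frequency is count over total; relative angular speed is frequency
times mean bin speed, so the relative angular speeds sum to the overall
mean retained speed.

The major angle is a least-squares Gaussian on (bin center, frequency)
after unwrapping the periodic axis around the modal bin; the fitted mean
is wrapped back to $[-180°, 180°)$. The fit needs at least 4 nonzero bins.
Condition comparisons use one-way ANOVA with Tukey HSD. Whether frequency
normalization should pool all frames per experiment or average per-frame
histograms is not prescribed; pooling is used, and per-frame analysis can
be had by passing single frames.

`block_velocimetry()` is a minimal normalized-cross-correlation block
matcher (32 px windows, 50% overlap) for exercising the pipeline on
synthetic image pairs end to end; it is not a replacement for a
full-featured PIV with multi-pass window deformation.
`segment_tissue()` thresholds local variance (box filter) and keeps the
largest connected component.

## Synthetic-data generators

Each generator is seeded (bit-reproducible; `split_seed()` derives
decorrelated per-generator streams from one top-level seed), emits a
machine-readable truth record, and emulates the acquisition structure its
analysis assumes:

* **SAIM** — per-pixel forward model $A F(h) + B$ over the standard
  14-angle 0–52° sweep with *multiplicative* Gaussian noise (camera gain
  variation dominates at these signal levels);
* **tweezer** — 1 pN/s ramp at 10 ms sampling, a smooth saturating
  force–height tether baseline, planted steps at set forces, additive
  Gaussian noise; events planted closer than one detector window are
  flagged;
* **FRAP** — 90 frames at 1 s with the bleach after frame 4; the bleached
  ROI drops by `bleach_depth` and recovers along $p(1-e^{-kt})$, both
  ROIs decay with acquisition photobleaching (0.2%/frame default),
  background constant. Additive Gaussian noise of SD `noise_sd` (in
  full-scale units) is applied to every bleached-ROI frame *except* the
  bleach (floor) frame, plus smaller noise on reference and background.
  The floor frame is part of the calibration scaffold the generator
  guarantees invertible: the full-scale calibration anchors to that single
  frame, and a noisy anchor propagates a common-mode distortion that
  biases every downstream fit (no estimator of the two-parameter recovery
  model is unbiased under it). Real traces *do* carry bleach-frame noise —
  single-frame anchoring is a known fragility of the full-scale formula —
  so recovery results on synthetic data bound what clean calibration can
  achieve rather than what noisy anchors deliver;
* **recoil** — frames every 2 s from −6 s to +30 s; separation grows
  linearly at the configured ballistic rate for the first two
  post-ablation frames, then saturates exponentially, so the noiseless
  first-2-s secant equals the configured rate by construction; positional
  Gaussian noise per coordinate;
* **migration** — von Mises directions about a set mean angle, Gaussian
  speeds truncated at zero, and a configurable fraction of sub-threshold
  (static) vectors.

The generators emulate the statistical structure the estimators assume —
not optical aberrations, drift, photophysics, asymmetric recoil, or
tissue mechanics. Passing recovery tests therefore demonstrates estimator
correctness and calibration under the stated noise models, not robustness
to every artifact of real acquisitions.

## Problem sizes and numerical choices

The validation suite uses 64×64 fields (4096 pixel fits per stack) for
SAIM recovery at 2% noise, 50 FRAP traces and 20 recoil tracks at the
published wild-type parameters, and 40–50 simulated ramps for detector
benchmarks — sizes at which every recovery distribution is tight enough to
compare against its target while the whole suite runs in about a minute.
One caveat is worth stating: with 86 post-bleach frames at noise SD 0.05,
the per-trace FRAP rate estimate has an information-bound (CRLB) relative
SD of ~19%, so a 50-trace mean of $\ln 2/\hat k$ carries an intrinsic
upward Jensen bias of about +1 s and a sampling SD of about 1.3 s; mean
half-lives recovered from 50 traces scatter accordingly, and that scatter
is a property of the design, not of the fitting code.

Key numeric defaults collected in one place: WLC inversion tolerance
$10^{-6}$ pN; SAIM restart grid 10 nm over [0, 200] nm, LM relative
tolerance $10^{-12}$, tie-break to the lowest height; step detector window
30 samples, significance 6, minimum step 10 nm, classification band
half-width 10 nm; FRAP bounds $p \le 1.5$, $k \le 10$ s$^{-1}$; angular
bins 30° with a 15° offset so 0° is a bin center; speed filter threshold
10 µm/h, boundary retained.
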