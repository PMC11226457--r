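# ajmech

Quantitative analysis of force transmission at adherens junctions, for
cell-mechanics labs working with scanning-angle interference microscopy
(SAIM), single-molecule magnetic tweezers, FRAP, junction laser ablation and
collective-migration velocimetry. The package bundles the five analysis
stages such studies chain together, each paired with a seeded synthetic-data
generator so every stage can be exercised and validated without any raw
data.

## What it computes

**SAIM axial nanometry.** A fluorophore at height *h* above a silicon
mirror with an oxide spacer is excited by the standing wave formed by the
direct and reflected beams. The per-angle excitation is

    F_j = | 1 + r(θ_j) e^{i φ_j} |²,   φ_j = 4π n_m h cos θ_j / λ,

with *r* the complex reflection coefficient of the medium/oxide/silicon
stack (single-film Airy optics). Measured intensities are fitted per pixel
as `I_j ≈ A·F_j(h) + B` by multi-start Levenberg–Marquardt; ROIs are
summarized by the median fitted height (`z_center`).

**Worm-like-chain rupture steps.** For a looped VBS–FH1–VD1 tweezer
construct, the bead-height step expected from unlooping and/or VD1 subunit
unfolding is the Marko–Siggia extension of the released contour at the
rupture force (persistence 0.8 nm, 0.38 nm/aa, kT at 37 °C), minus the span
of the formerly folded element. Steps detected on force-ramp traces by a
sliding-window change-point statistic are classified against these bands
(steps ≤ 35 nm are not attributed to complex dissociation).

**FRAP.** Double normalization corrects the bleached-ROI signal by the
reference ROI and background; full-scale calibration maps the pre-bleach
average to 1 and the bleach frame to 0; the recovery is fitted as
`I(t) = p(1 − e^{−kt})`, giving mobile fraction *p* and half-life ln2/k.

**Ablation recoil.** Inter-edge Euclidean distance per frame; the initial
recoil rate is the secant over the first 2 s after the cut.

**Migration angular statistics.** Velocity vectors slower than 10 µm/h are
discarded; directions are binned into 30° bins; per-bin frequency and
relative angular speed (frequency × mean bin speed) are summarized and the
major angle extracted by a Gaussian fit
`Y = A·exp(−0.5((X−Mean)/SD)²)`.

## Worked example

```r
library(ajmech)

# predicted rupture-step bands for the tweezer construct
predicted_step("unloop_only", c(7, 16))
#> [1] 39.13856 53.96422
predicted_step("unloop_full_unfold", 16)
#> [1] 111.7614

# simulate a SAIM stack at 51.67 nm with 2% noise and recover the z-center
sim <- sim_saim_stack(51.67, nrow = 64, ncol = 64, noise_frac = 0.02, seed = 7)
res <- fit_saim_stack(sim$image_stack)
roi_zcenter(res$height_map)
#> # A tibble: 1 × 4
#>   roi_id n_pixels n_nonfinite z_center_nm
#>   <chr>     <int>       <int>       <dbl>
#> 1 roi1       4096           0        51.7

# FRAP: simulate, normalize, fit
frap <- sim_frap_trace(p = 0.331, k = log(2) / 29.02, noise_sd = 0.05, seed = 1)
fit <- fit_frap_recovery(frap_normalize(frap$trace))
glance(fit)[, 1:3]
#> # A tibble: 1 × 3
#>   mobile_fraction      k half_life_s
#>             <dbl>  <dbl>       <dbl>
#> 1           0.326 0.0277        25.0
```

The step predictions say a bare unlooping event should change bead height
by ~39 nm at 7 pN and ~54 nm at 16 pN, while full VD1 unfolding on top of
unlooping exceeds 100 nm — the bands used to classify observed steps. The
SAIM round trip recovers the ground-truth height to well under a
nanometer at 2% image noise, and the FRAP fit returns the generating
mobile fraction and half-life within their sampling uncertainty.

A command-line front-end mirroring the R functions is installed at
`system.file("scripts", "ajmech", package = "ajmech")`, e.g.

```sh
ajmech simulate frap --out run1 --seed 7
ajmech frap-fit --trace run1/frap_trace.csv --bleach-index 4 --out run1/fit
```

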