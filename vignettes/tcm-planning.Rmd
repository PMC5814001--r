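---
title: "Attenuation-based tube current modulation for kV-CBCT: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attenuation-based tube current modulation for kV-CBCT: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctcm)
```

## The problem

Kilovoltage cone-beam CT mounted on a linac is acquired before (often every)
radiotherapy fraction to verify patient position. The imaging dose is not
negligible, and a full rotation spends the same tube output on every gantry
angle even though an anteroposterior view through a pelvis attenuates orders
of magnitude less than a lateral one. Tube current modulation (TCM) spends
photons where they are needed: more current for heavily attenuating views,
less elsewhere, at equal reconstructed noise. In the radiotherapy setting a
planning CT of the same patient already exists, so the per-angle attenuation
can be predicted *before* the scan — this package implements that
prior-knowledge planner end to end, together with the simulation and
evaluation machinery needed to test it.

## The model

For view $i$ of $P$ views, let $A_i \ge 1$ be the view attenuation factor:
the ratio of incident to transmitted quanta along the ray that dominates the
view, $A_i = e^{\int \mu \, dl}$, computed by exact Siddon traversal of the
prior attenuation map. A conventional scan spends its total quanta $N_0$
uniformly, $N_{0i} = N_0/P$. Under the standard quantum-noise model each
view contributes variance proportional to $A_i/N_{0i}$, so the conventional
scan's pixel noise variance is

$$\sigma^2_{\mathrm{ref}} \;=\; \sum_{i=1}^{P} \frac{A_i}{N_0/P}.$$

The planner minimizes total quanta $\sum_i N_{0i}'$ subject to
$\sum_i A_i/N_{0i}' = \sigma^2_{\mathrm{ref}}$. The Lagrange condition gives
$N_{0i}' \propto \sqrt{A_i}$, hence

$$N_0' = \frac{\left(\sum_i \sqrt{A_i}\right)^2}{\sigma^2_{\mathrm{ref}}},
\qquad
N_{0i}' = N_0' \frac{\sqrt{A_i}}{\sum_j \sqrt{A_j}},$$

and by the Cauchy–Schwarz inequality
$N_0'/N_0 = (\sum_i\sqrt{A_i})^2 / (P\sum_i A_i) \le 1$, with equality
exactly when all $A_i$ are equal: the plan can never cost more dose than the
uniform scan, and saves more the more eccentric the anatomy.

### Why square-root allocation is the default

The classical attenuation-proportional rule $N_{0i}' \propto A_i$ is kept as
`allocation_mode = "proportional"`, but it carries a small theorem worth
stating: once the proportional allocation is rescaled to match the reference
variance, its total is *identically* $N_0$ — writing $N_{0i}' = cA_i$, the
constraint $\sum_i A_i/(cA_i) = P/c = \sigma^2_{\mathrm{ref}}$ fixes
$c = N_0/\sum_i A_i$ and therefore $\sum_i N_{0i}' = N_0$ exactly. A
variance-matched proportional plan can never reduce dose. Since the method's
entire point is dose reduction at preserved noise, the variance-optimal
square-root reading is the default, and it reproduces the canonical
two-view example exactly: $A = (1, 4)$, $N_0 = 100$ gives
$\sigma^2_{\mathrm{ref}} = 0.1$, $N_0' = 90$, allocation $(30, 60)$, and a
modulated variance of $0.1$ — a 10% saving at identical predicted noise.

## The synthetic stated world

No licensed anthropomorphic phantom ships with the package; a deterministic
elliptical generator stands in for it.

* **Pelvis preset**: a 32 × 20 cm soft-tissue body ($\mu = 0.21$ /cm at the
  60 keV design energy), two *unequal* tilted iliac bone wings and a
  posterior sacrum ($\mu = 0.57$ /cm). The left/right bone inequality is
  deliberate: pelvic modulation curves are mirror-asymmetric in practice,
  and the tests assert exactly that. The square-root plan for this preset
  lands at ≈ 34% total-quanta reduction — the regime reported for pelvic
  TCM scans.
* **Abdomen preset**: a broad 33 × 18 cm body with a single vertebral body,
  mirror-symmetric, landing at ≈ 21% reduction.
* **Fluence scale**: the default protocol total ($N_0 = 10^{10}$ for 360
  views × 400 columns) corresponds to ≈ 7 × 10⁴ unattenuated quanta per
  detector element per view, a realistic flat-panel magnitude that keeps the
  worst-case transmitted count above ~10, so the zero-count clamp never
  fires in the default studies.

What the generator does *not* emulate — and what a green test therefore does
not establish — includes scatter, polychromatic beam hardening, detector
blur/lag and real anatomical texture. The forward model is monoenergetic
Beer–Lambert with independent Poisson counting noise; an optional bowtie
reshapes incident fluence across the fan.

## Numerical choices

* **Ray tracing** uses Siddon's parametric traversal, exact for the
  piecewise-constant voxel model; segment lengths are recovered from
  consecutive plane-crossing parameters and voxels identified by segment
  midpoints, which makes the traversal robust to coincident crossings.
  Near-axis trigonometric values are snapped to exact zero ($|\sin|,|\cos|
  < 10^{-12}$) so rays that run exactly along voxel-boundary planes (the
  central ray at gantry 90° on an even grid) resolve to a consistent side;
  without this the 180° periodicity of line integrals breaks at exactly the
  lateral angles.
* **Voxelization tolerances.** The chord through a voxelized disk jitters
  by about one voxel layer, i.e. 1–3% in $A$ at the default grids. Continuum
  identities (constant $A$ for a disk, equal all-view dose-proxy terms at
  the center) therefore hold only up to that bound at finite resolution; the
  tests assert the *exact* discrete dihedral symmetries (to $10^{-9}$) plus
  one-voxel-layer bounds, and convergence under grid refinement.
* **Zero-count handling**: transmitted counts below one are clamped to one
  before the log normalization (warning plus a clamp count in the result);
  an infinite line integral would otherwise propagate through the ramp
  filter.
* **Reconstruction**: equidistant flat-detector fan-beam FBP (single-row) or
  circular FDK (multi-row): cosine pre-weighting on the virtual detector
  through the isocenter, redundancy weighting (constant ½ for a full-fan
  2π scan; smooth $\sin^2$ transition weights over the overlap band for a
  displaced detector, so conjugate rays always sum to weight one), row-wise
  band-limited ramp filtering with zero-padding to the next power of two at
  least twice the column count (optional Hann apodization), and voxel-driven
  backprojection with the fan magnification weight $\mathrm{SAD}^2/U^2$.
  Filter apodization and padding are declared defaults, not inferences.
* **Noise metric**: the reported "NRMSE" is implemented exactly as the
  reference-free within-ROI coefficient of variation,
  $\mu^{-1}\sqrt{N^{-1}\sum_i (x_i-\mu)^2}$ with the population ($1/N$)
  variance — it needs no reference image (which is what makes a value for
  the ground-truth image itself meaningful), is scale-invariant, and is
  deliberately intensity-shift-variant; the tests pin that property down.
* **SSIM** follows the standard Gaussian-window formulation ($\sigma = 1.5$,
  11 × 11 taps, $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$, dynamic range $L$ from
  the reference, border of one window radius cropped); it is cross-checked
  against an independent reference implementation to $10^{-6}$.

## Open design points, resolved

* *Fan width for the beam-shape mode*: whether the averaged "actual beam
  shape" spans the full detector or only the collimated field is exposed as
  `fan_width` (default: full detector).
* *Central ray under a displaced detector*: the central-beam mode traces to
  the physical panel center ($u = $ lateral offset), which is off-isocenter
  in half-fan geometry; planner studies use full-fan geometry where the two
  coincide.
* *Quanta are continuous*: currents are a positive real proxy; conversion to
  mAs is a single user-supplied scale outside the model.
* *Config format*: JSON rather than TOML (no TOML parser in the supported
  runtime); structure and CLI flags are unchanged.
* *Volume input*: NIfTI only. DICOM-series reading is declared unsupported
  (no DICOM stack available to build against) and raises a clear error.

## Known limitations

The planner's noise model is anchored to a single ray per view. When the
attenuation dynamic range within the fan becomes extreme (hundreds-fold),
the per-view factor stops representing the detector-wide noise contribution
and the modulated scan's realized noise can drift several percent above the
matched prediction; at the presets' realistic 20–60× spreads the end-to-end
noise ratio stays within a few percent of unity (the test suite enforces
[0.9, 1.1] over 20 seeded repetitions). Scatter, beam hardening, organ-level
Monte Carlo dosimetry and scanner control are out of scope; the dose proxy
is a primary-fluence surrogate meaningful only for relative comparisons.

## A worked run

```{r example, eval = FALSE}
ph <- phantom_preset("pelvis")
geom <- scan_geometry(100, 150, n_cols = 400, pitch = 0.225, angles = 0:359)
prof <- view_attenuation(ph, geom, mode = "central")
plan <- plan_currents(prof, N0 = 1e10)
plan

proj <- simulate_projections(ph, geom, plan, "tcm", noise = "on", seed = 1)
rec <- reconstruct(proj, ph)
nrmse(rec, roi_spec("soft-tissue", "ellipse", c(128.5, 128.5), c(18, 18)))
```

The same workflow, both arms plus metrics and dose proxy, is available as
`run_pipeline()` and through the `inst/cli/cbctcm` command-line front end.
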