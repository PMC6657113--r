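---
title: "Quantifying intraventricular flow energetics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intraventricular flow energetics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventriflow)
```

## The measurement model

4D flow CMR reconstructs a velocity vector $v(x, t)$ (m/s) on a regular
voxel grid over a representative cardiac cycle, typically 30 phases under
retrospective gating, together with a per-phase binary segmentation of the
ventricular cavity. Three volume-integrated markers are computed per
phase, over the in-mask voxels only:

$$\mathrm{KE}(t) = \sum \tfrac12\,\rho\,dV\,|v|^2, \qquad
\mathrm{EL}(t) = \mu \sum dV\,\phi_v, \qquad
\mathrm{vorticity\_vol}(t) = \sum |\nabla\times v|\,dV,$$

with $dV$ the voxel volume and

$$\phi_v = \tfrac12 \sum_{i,j}\Big[\Big(\partial_j v_i + \partial_i v_j\Big)
  - \tfrac23(\nabla\cdot v)\,\delta_{ij}\Big]^2 .$$

$\phi_v$ is the dissipation function of the Navier–Stokes energy equation
for a Newtonian fluid. The $-\tfrac23(\nabla\cdot v)\delta_{ij}$ term is
kept because measured, noisy velocity fields are never exactly
divergence-free; on solenoidal analytic flows it vanishes, so it does not
perturb the closed-form validation. The vorticity integral takes the
magnitude voxel-wise *before* summation: counter-rotating structures add
rather than cancel, which is the intended reading of a "total rotational
content" marker (verified by a dedicated two-core test).

Each series is averaged over systolic frames, diastolic frames and the
full cycle with equal phase weights — retrospective gating spaces phases
uniformly across the RR interval, so equal weighting equals time
weighting. Cycle averages are optionally divided by stroke volume
(KE/SV in mJ/mL, EL/SV in mW/mL, vorticity_vol/SV in 1/s).

### Physical parameters

| parameter | default | units | rationale |
|---|---|---|---|
| $\rho$ | 1.025 | g/mL | standard blood density used in CMR energetics |
| $\mu$ | $4.0\times10^{-3}$ | Pa·s | common Newtonian approximation for blood at high shear; configurable, since hematocrit-adjusted values are sometimes preferred |
| VENC | per acquisition | m/s | velocity-encoding limit; values beyond ±VENC alias by $2\,\mathrm{VENC}$ |

Internally everything is SI (velocities m/s, lengths m); spacing is
carried in mm as NIfTI headers store it, and outputs are scaled to
mJ / mW / mL/s only at the reporting boundary.

## Numerical choices

**Masked gradients.** All derivatives are second-order central
differences, except where a stencil neighbour falls outside the
segmentation: there a first-order one-sided difference is used, and a
voxel with no in-mask neighbour along an axis gets a zero derivative on
that axis. Stencils never read velocities outside the chamber, which are
undefined tissue/noise voxels. The one-sided fallback costs accuracy
exactly where wall shear peaks, which is why the Poiseuille energy-loss
benchmark converges at roughly first order in voxel size (relative error
5.4% → 1.1% → 0.25% on 32³ → 64³ → 128³ grids); the suite asserts the
error is strictly decreasing under refinement rather than a fixed
asymptotic rate.

**Aliasing correction.** `wrap_velocity` is the exact forward model of
phase wrapping, $v \mapsto ((v + \mathrm{VENC}) \bmod 2\,\mathrm{VENC}) -
\mathrm{VENC}$. The corrector grows a breadth-first region per connected
mask component, seeded at the voxel of smallest speed, and shifts any
voxel differing from the median of its already-corrected in-mask
6-neighbours by more than VENC by $\pm2\,\mathrm{VENC}$. The design is
deliberately *propagating*: a coherently wrapped core (e.g. the centre of
a jet at VENC = 0.75·v_max) is locally self-consistent, so a one-pass
neighbourhood-threshold rule finds nothing to fix; only information
carried inward from unaliased flow can resolve it. The slowest-voxel seed
leans on no-slip physics — near-wall velocities approach zero, safely
below VENC. With single wraps and true voxel-to-voxel velocity jumps
below VENC the reconstruction is exact; multiple wraps
($|v| > 2\,\mathrm{VENC}$) are out of scope, as they are for the
interactive tools this replaces.

**Volumetrics.** EDV and ESV are the maximum and minimum of the
voxel-count volume curve — the volume-extremum convention, chosen for
determinism over ECG-timing conventions. SV, EF and CO follow as exact
identities. Sphericity is the ratio of axis-aligned bounding-box extents
(width axis / long axis) at the ED and ES frames; clinical practice often
measures it on 2D cine views, so the 3D bounding-box variant is a
documented difference, not an equivalence claim.

**Rigid mask alignment.** A given rotation+translation is applied by
nearest-neighbour resampling on the mask's own grid (binary in/out, no
partial-volume weighting); voxels mapping outside the grid become
background. Estimating the registration is explicitly out of scope.

**Degenerate inputs.** Constant difference vectors make both paired tests
degenerate; `paired_compare` returns $p = 1$ with a warning. A constant
sample is reported non-normal by the gate (the Shapiro–Wilk statistic is
undefined there). Zero rest values make a relative difference undefined;
they become `NA` with a warning rather than an error so one degenerate
subject cannot abort a cohort. A non-beating mask (SV = 0) yields `NA`
SV-normalized values in the subject pipeline.

## The statistical stage

Per metric, per-subject differences $d =$ stress − rest are gated by the
Shapiro–Wilk test at $\alpha = 0.05$: normal $\to$ paired $t$;
non-normal $\to$ Wilcoxon signed-rank (exact null distribution for
$n \le 25$, normal approximation with continuity correction above).
Summaries follow the same gate: mean ± SD (sample, $n-1$) when normal,
median [IQR] otherwise. The gate is applied to the difference vector, not
to each arm — the variance-relevant quantity for a paired test.
Correlation of each metric's relative difference with VO₂max uses Pearson
when *both* variables pass the gate and Spearman otherwise (the
conservative reading of "in case of non-normality"); an explicit
`method=` override bypasses the gate, which matters when validating
recovery of a planted Pearson correlation — the auto path occasionally
(at the gate's own false-positive rate) switches to the Spearman
estimator, whose population target for bivariate normal data is
$\tfrac{6}{\pi}\arcsin(\rho/2)$, not $\rho$. Strength labels follow the
conventional scale on $|r|$ (>0.95 excellent, 0.95–0.85 strong, 0.85–0.70
good, 0.70–0.5 moderate, <0.5 poor), with boundary values assigned to the
lower-strength side; two-sided tests throughout, no multiplicity
correction.

## What the synthetic data emulate — and what they do not

The phantoms exist so that every pipeline stage has an exact target:

- **uniform flow** — KE $=\tfrac12\rho V|v|^2$ exactly; EL and vorticity
  identically zero (constant field);
- **rigid rotation** — linear in position, so central differences are
  exact: $|\nabla\times v| = 2\Omega$, EL $= 0$ to machine precision;
- **Poiseuille pipe** — EL $= 2\pi\mu L v_{max}^2$,
  KE $= \rho v_{max}^2 V/6$, vorticity_vol $= \tfrac43 v_{max} V/R$;
- **Lamb–Oseen vortex** — single-signed vorticity integrating to
  $\Gamma L$ once the mask radius exceeds $4r_c$ (the tail beyond carries
  $<10^{-6}$ of $\Gamma$).

Pulsatility multiplies a base field by per-phase scale factors, keeping
per-phase oracles analytic (KE and EL scale as $s^2$, vorticity as
$|s|$). The beating-ellipsoid mask interpolates semi-axes linearly from
end-diastole (phase 1) to end-systole (last systolic frame) and back,
giving analytic per-phase volumes $\tfrac43\pi abc$; the linear-in-axes
profile is a deliberate simplification of ventricular contraction
patterns.

The cohort simulator draws VO₂max $\sim N(30.2, 8.6^2)$ mL/kg/min and
positive rest metrics (KE $1.8 \pm 0.5$ mJ, EL $0.9 \pm 0.4$ mW,
vorticity_vol $3441 \pm 899$ mL/s — a small Fontan cohort's operating
point), plants a linear model for the relative rest-to-stress change
$\Delta\% = a + b\cdot\mathrm{VO_2max} + \varepsilon$, and sets
stress $=$ rest $\cdot(1 + \Delta/100)$ *exactly*, so the table's
relative differences recompute to the planted values bit-for-bit. The
default slope/intercept/noise per metric are derived once from target
difference distributions ($88 \pm 52\%$, $108 \pm 49\%$, $27 \pm 19\%$)
and correlations ($-0.83$, $-0.80$, $-0.64$) via
$b = r\,\sigma_\Delta/\sigma_{\mathrm{VO_2}}$,
$\varepsilon \sim N(0, \sigma_\Delta^2(1-r^2))$.

None of this emulates real intracardiac flow: there is no chamber-shaped
geometry, no CFD, no MR noise physics beyond additive i.i.d. Gaussian
velocity noise, no eddy-current offsets, and no turbulent kinetic energy
(incoherent within-voxel velocity spread is invisible to the mean-velocity
model entirely). Passing phantom tests therefore demonstrates that the
*numerics* — integration, stencils, units, gating, reporting — are
correct at their stated tolerances; it says nothing about segmentation
quality or sequence-dependent bias in real acquisitions.

## Problem sizes and reproducibility

The validation suite runs phantoms at 20³–64³ voxels (one refinement
check at 128³), statistical calibration on 2000 simulated null cohorts of
$n = 10$ and planted-correlation recovery at $n = 200$ — sizes chosen so
the full suite completes in well under a minute per module while leaving
the discretization tolerances comfortably resolvable. All random draws
flow through explicit integer seeds (`cohort_spec(seed=)`,
`add_noise(seed=)`), and seeded runs restore the caller's RNG state, so
identical inputs give bit-identical outputs.

## Known limitations

- First-order accuracy at mask boundaries; strongly non-convex or
  one-voxel-thin masks degrade the gradient quality further.
- The unwrapper assumes single wraps and smooth flow; pathological fields
  whose true neighbouring velocities differ by more than VENC can defeat
  the median criterion.
- Phase partitions are inputs; the package does not derive systole from
  flow-time curves.
- Sphericity from 3D bounding boxes is not interchangeable with 2D cine
  measurements.
- Nearest-neighbour mask resampling quantizes small rotations; volumes
  are preserved only to voxelization error (~2% on typical grids).
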