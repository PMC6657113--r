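# ventriflow

Intraventricular flow energetics and vorticity from 4D flow cardiovascular
MRI.

Time-resolved three-dimensional phase-contrast CMR ("4D flow") measures a
three-component velocity vector in every voxel of the heart at every
reconstructed cardiac phase. In patients with abnormal intracardiac flow —
the motivating case is the single-ventricle Fontan circulation under rest
and pharmacologic (dobutamine) stress — three volume-integrated markers
summarize how efficiently the ventricle handles blood:

- **Kinetic energy.** Per phase, over the segmented chamber,
  `KE = Σ ½ ρ dV |v|²`, with blood density ρ = 1.025 g/mL, reported in mJ.
- **Viscous energy loss.** The rate of irreversible dissipation from the
  Newtonian Navier–Stokes energy equation,
  `EL = μ Σ dV φᵥ`, with
  `φᵥ = ½ Σᵢⱼ [(∂vᵢ/∂xⱼ + ∂vⱼ/∂xᵢ) − ⅔(∇·v)δᵢⱼ]²`,
  dynamic viscosity μ = 4.0·10⁻³ Pa·s by default, reported in mW. The
  divergence term compensates for measured fields not being exactly
  solenoidal; for analytic flows it vanishes.
- **Volumetric vorticity.** `vorticity_vol = Σ |∇×v| dV` in mL/s —
  magnitude before integration, so counter-rotating structures do not
  cancel.

All spatial derivatives use central differences that never reach across
the segmentation boundary (one-sided fallback at edge voxels). Each series
is averaged over the systolic frames, the diastolic frames and the full
cycle, and optionally normalized by stroke volume.

Around this core the package provides:

- NIfTI I/O for velocity triplets and 4D binary masks (`RNifti`), subject
  configs in YAML/JSON, rigid mask alignment, and VENC aliasing tools
  (`wrap_velocity`, region-growing `unwrap_velocity`);
- chamber volumetrics from the mask series: EDV, ESV, SV = EDV−ESV,
  EF = 100·SV/EDV, CO = SV·HR, and sphericity (width/height) indices;
- analytic phantoms with closed-form reference values — uniform flow,
  rigid rotation (`vorticity_vol = 2ΩV`, EL = 0), Poiseuille pipe flow
  (`EL = 2πμLv²`, `KE = ρv²V/6`), Lamb–Oseen vortex
  (`vorticity_vol = ΓL`) — plus beating-ellipsoid masks, Gaussian noise
  and a paired rest/stress cohort simulator with a planted
  VO₂max association;
- the cohort statistics used in rest–stress studies: Shapiro–Wilk-gated
  paired t / Wilcoxon signed-rank tests, mean ± SD vs median [IQR]
  summaries, relative differences, Pearson/Spearman correlation with
  VO₂max, and the strength classification
  (>0.95 excellent, 0.95–0.85 strong, 0.85–0.70 good, 0.70–0.5 moderate,
  <0.5 poor).

## Worked example

Poiseuille pipe flow (R = 10 mm, L = 50 mm, v_max = 1 m/s) sampled on a
64³ grid, compared with the closed forms:

```r
library(ventriflow)
g  <- voxel_grid(64, 64, 64, dx = 24/64, dy = 24/64, dz = 52/64, nt = 1)
ph <- make_poiseuille(g, R_mm = 10, L_mm = 50, v_max = 1)
kinetic_energy(ph$field, ph$mask)    # 2.704 mJ   (closed form 2.683)
energy_loss_rate(ph$field, ph$mask)  # 1.271 mW   (closed form 1.257)
vorticity_vol(ph$field, ph$mask)     # 2120 mL/s  (closed form 2094)
```

A simulated ten-subject rest/stress cohort run through the full
statistical stage:

```r
tab <- simulate_cohort(cohort_spec(seed = 42))
run_study(tab)
#> rest-stress study report: 10 subjects, 0 excluded
#>   metric          rest        stress    difference difference_pct p_value
#> 1     ke  1.72 ± 0.815    2.8 ± 1.46  1.08 ± 0.799    59.2 ± 36.9 0.00209
#> 2     el 0.859 ± 0.343  1.61 ± 0.769 0.751 ± 0.495    86.3 ± 35.6 0.00098
#> ...
#> relative difference vs VO2max:
#>   metric      r  p_value  method strength
#> 1     ke -0.578 0.080    pearson moderate
#> 2     el -0.725 0.018    pearson     good
#> 3   vort -0.527 0.117   spearman moderate
```

Each row compares rest against stress with the test selected by the
normality gate; the correlation block relates each metric's relative
rest-to-stress change to exercise capacity (VO₂max). At n = 10 the
per-seed correlation estimates scatter widely around the simulator's
planted values — exactly the sampling behaviour a small cohort exhibits.

A thin CLI over the same functions lives at `inst/cli/ventriflow.R`
(`phantom`, `cohort`, `subject --config cfg.yaml --condition rest`,
`study --cohort cohort.csv`).

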