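---
title: "Characterizing photobioreactor surfaces: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing photobioreactor surfaces: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbrsurf)
```

`pbrsurf` converts three streams of bench measurements — sessile-drop
contact angles, displacement-resolved zeta potentials, and adhered-mass
assays — into the quantities used to rank construction materials of
microalgal photobioreactors by biofouling propensity. This vignette is
the package's account of the underlying models, the conventions and
numerical choices it commits to, and what its tests do and do not
establish.

## The acid–base surface-energy model

The van Oss–Chaudhury–Good (vOCG) framework splits a surface free
energy into a Lifshitz–van der Waals component $\gamma^{LW}$ and Lewis
acid–base parameters $\gamma^{+}$ (electron acceptor) and $\gamma^{-}$
(electron donor), with $\gamma^{AB} = 2\sqrt{\gamma^{+}\gamma^{-}}$ and
$\gamma = \gamma^{LW} + \gamma^{AB}$. For a probe liquid $L$ on solid
$s$, the Young–Dupré equation is

$$\gamma_L (1+\cos\theta_L) = 2\left(\sqrt{\gamma_s^{LW}\gamma_L^{LW}}
 + \sqrt{\gamma_s^{+}\gamma_L^{-}} + \sqrt{\gamma_s^{-}\gamma_L^{+}}\right).$$

Assumptions inherited from the framework: smooth, rigid, homogeneous
solids; no liquid penetration or swelling; equilibrium (advancing)
angles; geometric-mean combining rules. Roughness violates the first
assumption in a controlled way — that is in fact the experimental
variable the adhesion assay manipulates — so energies computed for
rough surfaces are *apparent* quantities on the Wenzel-composite
surface, useful for ranking rather than as intrinsic material
constants.

With an apolar liquid (diiodomethane, $\gamma^{+}=\gamma^{-}=0$) the
system decouples: $\gamma_s^{LW}=\gamma_D(1+\cos\theta_D)^2/4$, then
water and formamide give a linear $2\times2$ system in
$a=\sqrt{\gamma_s^{+}}$, $b=\sqrt{\gamma_s^{-}}$. `solve_components()`
implements exactly this; `vocg()` wraps it into a fit object with the
usual methods (`coef`, `predict`, `residuals`, `simulate`, `plot`).

### Probe-liquid constants

The defaults (mJ m⁻², water 72.8/21.8/25.5/25.5, formamide
58.0/39.0/2.28/39.6, diiodomethane 50.8/50.8/0/0) are the van Oss
reference values with the conventional equal split of water's acid and
base parameters. Published sets differ slightly, particularly for
formamide; this set is the one validated against the package's built-in
benchmark table (`reference_surfaces()`), which it reproduces within
the propagated angle-rounding error — it was *not* validated against
any particular literature citation for the constants themselves.
Alternative constants go through the `liquids:` section of a run
configuration; the registry itself is never mutated.

### The negative-root (magnitude) convention

For strongly monopolar polymer surfaces — most commodity plastics are
electron-donor monopolar — the linear solve routinely returns
$a = \sqrt{\gamma_s^{+}} < 0$. The three equations then have no exact
solution with non-negative components, and some convention is required.
`pbrsurf` carries the magnitudes: $\gamma^{+}=a^2$, $\gamma^{-}=b^2$,
$\gamma^{AB}=2|a||b|$, with the same magnitudes entering every
$\Delta G_{coh}$ cross term. This choice was validated empirically: it
is the only convention that reproduces the benchmark totals for the
negative-root materials (e.g. polycarbonate $\gamma_s = 57.1$,
transparent PVC $45.0$ mJ m⁻²). The alternative (clamping the negative
root to zero) yields visibly different totals. Because the convention
is physically debatable, every result carries `root_neg_plus` /
`root_neg_minus` audit flags, `residuals()` quantifies the resulting
Young–Dupré imbalance (exactly zero when both roots are non-negative),
and the pipeline warns per affected surface.

Replicates are averaged to one mean angle triple per surface *before*
inversion, matching how goniometer data are reported (mean ± SD,
n = 3); replicate SDs feed only the synthetic-recovery machinery.

### Cohesion free energy, adhesion tension, classifications

$\Delta G_{coh} = -2\gamma_{sw}$ with
$\gamma_{sw} = (\sqrt{\gamma_s^{LW}}-\sqrt{\gamma_w^{LW}})^2 +
2(\sqrt{\gamma_s^{+}\gamma_s^{-}} + \sqrt{\gamma_w^{+}\gamma_w^{-}} -
\sqrt{\gamma_s^{+}\gamma_w^{-}} - \sqrt{\gamma_s^{-}\gamma_w^{+}})$.
A water-like solid gives exactly zero; positive values mark hydrophilic
surfaces. The Vogler classification uses the water adhesion tension
$\tau_0 = \gamma_w\cos\theta_w$ with a strict threshold,
hydrophilic iff $\tau_0 > 30$ mJ m⁻² (the boundary value itself
classifies hydrophobic, matching the strict inequality the criterion is
stated with). The Baier minimal-fouling window is not a sharply defined
number in the literature; the default closed interval
$[20, 30]$ mN m⁻¹ is the range usually quoted for the Baier minimum and
is exposed as a parameter.

### The critical surface tension and its limits

`critical_surface_tension()` is a plain Zisman construction: OLS of
$\cos\theta_i$ on $\gamma_{L,i}$, extrapolated to $\cos\theta = 1$.
With only three chemically disparate liquids this line is often a poor
fit (acid–base interactions are liquid-specific), so the fit $r^2$ is
returned and the pipeline warns below 0.9 instead of silently dropping
liquids. Notably, the $\gamma_c$ values carried in
`reference_surfaces()` are **not** reproducible by this construction
from the tabulated angles — for the glass row the OLS line crosses
$\cos\theta=1$ near 90 mJ m⁻² against a reported 56.7 — so the
originally used procedure evidently differed (it was likely restricted
to, or anchored on, a different liquid subset). The package therefore
treats reported $\gamma_c$ as reference metadata only; its own
$\gamma_c$ is asserted exactly on synthetic angle sets generated from a
true Zisman line, plus the degenerate-slope error path. Zero slope
(all $\cos\theta$ equal) raises an error rather than returning an
infinite extrapolation.

## Surface zeta potential

Dip-cell measurements report a tracer's apparent zeta potential at
increasing displacement from the sample: electro-osmosis dominates near
the wall, tracer electrophoresis far away. The model is deliberately
linear — apparent zeta regressed on displacement over the near-wall
points (125–625 µm in the standard protocol), extrapolated to the wall:
$\zeta_s = -\text{intercept} + \zeta_m$, with $\zeta_m$ the far-field
(1000 µm) tracer value. The far-field point is *excluded* from the
regression: it estimates the tracer's own mobility, not the wall flow,
and would otherwise bias the intercept. No exponential-decay model is
fitted, and no Smoluchowski/Henry conversion is attempted — the
instrument's mobility-to-zeta step is upstream of this package. Signs
are reported as measured; negative $\zeta_s$ means a negatively charged
wall.

## Orbital shear rate

For coupons on the bottom of an orbitally shaken dish the average shear
rate is modelled as
$\gamma_\omega = r_{eff}\sqrt{\rho(2\pi f)^3/\mu}$, an $f^{3/2}$ law.
$r_{eff}$ is a lumped effective orbital length: the default 0.0275 m is
the unique value reproducing the documented triple 329/931/1712 s⁻¹ at
50/100/150 rpm for water in the standard dish geometry (85 mm dish,
3 cm orbit, 9 mm liquid height). Whether it "is" the orbit radius, the
dish radius or a composite cannot be separated within the lumped model;
it is therefore an explicit parameter with this provenance, not a
hard-coded constant. The model assumes non-breaking waves with full
bottom coverage; outside that regime (very high rpm or shallow liquid)
it extrapolates meaninglessly.

## Adhesion statistics

Adhered EPS mass per area is normalized to a control surface
(`relative_adhesion()`, control = 100 %); the control is configured,
not hard-coded, though the benchmark convention is borosilicate glass
at 3.0 µg cm⁻². Groupings use one-way ANOVA (delegated to
`stats::aov`) with Fisher's LSD at $\alpha = 0.05$:
$LSD = t_{1-\alpha/2,df_e}\sqrt{2\,MSE/n}$, with the harmonic mean of
group sizes for unbalanced designs (the benchmark design is balanced,
n = 3, so this only affects generality). The compact-letter display
uses the insert-and-absorb algorithm; ties are broken by the treatment
order of the input, making the letters deterministic. Zero within-group
variance is handled explicitly: the p-value is reported as undefined
and letters fall back to exact-tie comparison rather than dividing by a
zero MSE. Fisher's LSD is unprotected against multiplicity beyond the
omnibus F; it is the grouping convention of this assay family, not a
recommendation for many-group designs.

## The synthetic-data generators

Each generator mirrors one instrument stream at the benchmark study's
conditions, which are fixed as defaults and not tuned per analysis:

- **Contact angles** (`synth_contact_angles`): true angles from the
  forward Young–Dupré map of a component truth set; replicate noise is
  Gaussian *on the angle in degrees* (SD default 2°, the middle of the
  1–5° replicate SDs typical of sessile-drop triplicates), n = 3,
  clamped to [0, 180). Noise on angles, not on cosines, matches how
  replicate scatter is reported. The bundled truth library
  (`synth_truth_library()`) holds the six benchmark materials'
  components with negative roots projected to zero — a truth set must
  be forward-physical, and magnitude components of monopolar surfaces
  are not.
- **Zeta profiles** (`synth_zeta_profiles`): linear near-wall profiles
  over {125, 250, 375, 500, 625} µm plus the 1000 µm tracer row,
  Gaussian noise (default SD 1 mV) on the near-wall points.
- **Adhesion** (`synth_adhesion`): Gaussian replicate masses with a
  coefficient of variation (default 0.03, matching a 3.0 ± 0.1
  µg cm⁻² control) on the 18.75 cm² coupon (2.5 × 7.5 cm), n = 3,
  truncated at zero mass.

All generators are pure functions of their arguments and seed, and
restore the global RNG state. What they deliberately do **not**
emulate: angle-dependent (heteroscedastic) goniometer error, roughness
feedback on contact angles (Wenzel/Cassie), electro-osmotic
non-linearity near the wall, adsorption kinetics, or EPS degradation
under shear/ultrasound. Passing recovery tests on this synthetic family
therefore shows the *estimators* are correct and unbiased under the
assumed noise model — not that the physical models capture every
feature of real measurements.

## Numerical choices and degenerate inputs

- Trigonometry uses `cospi()` on degree inputs for exact values at 0,
  90, 180°; forward cosines are clamped to [−1, 1] only within 1e-9
  (pure floating-point overshoot), anything beyond raises an
  "unphysical component set" error (`forward_angles`) or returns `NA`
  with a warning (`predict`).
- The polar 2×2 system raises a "singular" error (determinant < 1e-10)
  naming the liquid pair, rather than returning an ill-conditioned
  solve.
- Benchmark regression tolerances: the benchmark angles are printed to
  1°; propagating ±0.5° rounding through the inversion moves
  $\gamma_s$ and $\tau_0$ by a few tenths of mJ m⁻² but
  $\Delta G_{coh}$ by up to ~2.5 mJ m⁻² for the steep-angle rows, so
  the full-table regression test uses ±2.5 while the well-conditioned
  headline rows are held to ±0.5.
- Test problem sizes: 1000-case noise-free inversion round trips
  (identity to 1e-6), 20-case agreement with an independent
  Levenberg–Marquardt least-squares oracle, 200-profile zeta
  Monte-Carlo (mean recovery within 0.5 mV), 500-assay LSD power check
  (1.5× control, cv 0.03, n = 3, separation required in ≥ 95 %), and
  100 random designs against a textbook sums-of-squares ANOVA oracle
  at 1e-9. These sizes make the statistical assertions stable across
  seeds while keeping the default suite fast.

## Known limitations

- The magnitude convention for negative roots is a convention; on
  strongly monopolar surfaces $\gamma_s$ comparisons between packages
  using different conventions will disagree systematically.
- $\gamma_c$ from three liquids is a diagnostic-grade quantity here;
  quantitative Zisman work needs a homologous liquid series.
- The shear-rate model is a lumped engineering correlation, valid for
  the calibrated dish/orbit geometry and non-breaking waves.
- No two-way material × roughness ANOVA is provided; the grouping
  machinery is one-way by design.
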