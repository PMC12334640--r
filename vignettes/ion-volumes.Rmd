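---
title: "Partial molar volumes of electrolytes and single ions: models, fitting choices and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial molar volumes of electrolytes and single ions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionvol)
```

## The problem

When a strong electrolyte dissolves in water it dissociates into hydrated
ions, and the volume the solution gains per mole of solute — extrapolated
to infinite dilution, the *partial molar volume* $V_2^0$ — reports on how
the ions reorganize the hydrogen-bond network around them. Kosmotropic
(high charge density) ions compress their hydration shells, sometimes so
strongly that $V_2^0$ is negative; chaotropic ions do the opposite. The
temperature dependence of $V_2^0$ carries additional structure: its
curvature reflects how thermal randomization of the solvation shell
competes with packing, and it turns out to differ in sign between cations
and anions.

`ionvol` implements the complete analysis chain for extracting these
quantities from high-precision densimetry of *dilute* solutions
($10^{-3}$–$3\times10^{-2}$ mol/kg), decomposing them into single-ion
contributions, and estimating the same quantities independently from
molecular-dynamics-style solvation snapshots. Because the raw laboratory
data and trajectories of the motivating study are not distributed with
the package, every estimator ships with a synthetic-data generator that
reproduces the statistical structure the estimator assumes, so the whole
pipeline is validated by parameter recovery.

## The density model

For a salt of molar mass $M$ at molality $m$, solution density $d$ and
solvent density $d_0$, the apparent-volume relation corrected by the
Debye–Hückel theoretical slope for volumes reads

$$
V_2^0(T) + A_v(T)\,\omega\,\frac{\ln\!\left(1 + b\sqrt{\omega m}\right)}{b}
 \;=\; \frac{M}{d_0} - \frac{10^3}{d\,d_0}\,\frac{d - d_0}{m},
$$

where $\omega = \tfrac12\sum_i n_i z_i^2$ is the valence factor and
$A_v(T)$ the temperature-dependent Debye–Hückel volume slope. The
right-hand side is exactly what the densimeter measures; the left-hand
side separates the infinite-dilution volume from the theoretically known
ion–solvent electrostatic contribution. Solving for $d$ gives a *closed
form* (not an approximation):

$$
d = \frac{d_0'}{1 - m\,\bigl(M - d_0' V_\psi\bigr)/10^3},
\qquad V_\psi = V_2^0(T) + \text{DH term},
$$

with $d_0' = d_0(T) + \Delta d_0$. This inversion is what
`predict_density()` evaluates and what the fits minimize against; the
package tests verify the round trip to $10^{-9}$ cm³/mol against an
independent bisection inversion.

The temperature dependence is quadratic,

$$
V_2^0(T) = V_2^0(T_\mathrm{ref}) + \alpha_2^0\,(T - T_\mathrm{ref})
 + \beta_2^0\,(T - T_\mathrm{ref})^2 , \qquad T_\mathrm{ref} = 25\ °C,
$$

where $\beta_2^0$ is everywhere the *quadratic coefficient* (half the
second derivative). The printed proton row of the ionic reference table
($-0.17\times10^{-3}$ from $-1.7\times10^{-4}\,T^2$) fixes this
convention unambiguously, and the package uses it for every solute and
ion.

### Parameters that matter

* **$A_v(T)$** (cm³·kg$^{1/2}$·mol$^{-3/2}$). Compilations differ at the
  ~10 % level. The default table is a smooth interpolation anchored at
  the widely tabulated Pitzer-convention values $A_v(0)=1.504$ and
  $A_v(25)=1.875$. A second built-in table (`av_slope_table("study")`,
  $A_v(25)=1.65$) reproduces the motivating study's printed effective
  Debye–Hückel contributions of 0.26, 1.25 and 1.90 cm³/mol at
  $m = 0.03$ mol/kg for $\omega = 1, 3, 4$ — the default table gives
  values ~14–15 % higher. At $m \le 0.03$ mol/kg the choice shifts
  fitted $V_2^0$ by far less than the fit uncertainty, which is why both
  tables are acceptable and configurable.
* **$b$** (kg/mol)$^{1/2}$. The standard Pitzer value $b = 1.2$ is used.
  The literature value is sometimes printed with units
  (g/mol)$^{1/2}$ and a $10^{-3}$ factor, which is dimensionally
  inconsistent with molality in mol/kg; $b=1.2$ (kg/mol)$^{1/2}$ makes
  $b\sqrt{\omega m}$ dimensionless and reproduces the printed
  contributions, so it is adopted (and exposed in
  `reference_context()`).
* **$d_0(T)$**. Kell's (1975) polynomial for air-free water at
  atmospheric pressure, which agrees with CRC reference values to
  $2\times10^{-5}$ g/cm³ on 20–40 °C. (Note the physical difference
  $d_0(20)-d_0(40)$ is 0.005988 g/cm³ — just below 0.006.)
* **$\Delta d_0$** (g/cm³). Each dilution series at each temperature
  carries a small offset between the asymptotic solvent density and the
  reference value (dissolved air, calibration drift). One nuisance
  offset per (series, temperature) is fitted — the granularity the
  study describes — with a switch for one per series. Offsets above
  the reported ceiling $2\times10^{-5}$ g/cm³ are flagged.
* **Instrument noise**: $7\times10^{-6}$ g/cm³ (declared densimeter
  precision). Since a single instrument measured everything, the
  objective is *unweighted* least squares on density residuals.

### Fitting

`fit_salt()` fits $(V_2^0, \alpha_2^0, \beta_2^0)$ globally across all
series and temperatures of one solute, plus the local $\Delta d_0$
nuisance parameters, by Levenberg–Marquardt with analytic Jacobians
(relative tolerance $10^{-12}$; failure to converge is an error).
Initialization is from the median apparent volume — the problem is
nearly linear, so any sane start converges. The covariance is the
Gauss–Newton $(J^\top J)^{-1} s^2$. Both the linear ($\beta_2^0 = 0$)
and quadratic models are always fitted; `model_order = "auto"` selects
the quadratic one only when both AIC and the F-test at $\alpha = 0.05$
favor it. On synthetic data at the study design, Monte-Carlo calibration
shows the selection rate under a linear truth at or below the nominal
5 % and a $V_2^0$ standard error of ~0.1 cm³/mol, matching the printed
per-salt uncertainties.

`extremum_temperature()` reports $T_\mathrm{ref} - \alpha/(2\beta)$,
the vertex of the quadratic. For some printed salt rows this value
disagrees with the printed extremum column (e.g. NaCl: 29 °C printed
vs ≈42 °C from the printed coefficients); the package always computes
from the parameters and flags vertices outside 20–40 °C as
extrapolations.

## Single-ion decomposition

Ionic additivity, $V_2^0(\mathrm{X}_n\mathrm{Y}_m) = n V_2^0(\mathrm{X})
+ m V_2^0(\mathrm{Y})$, turns sixteen binary salts of
{Li⁺, Na⁺, K⁺, Mg²⁺} × {Cl⁻, Br⁻, I⁻, SO₄²⁻} into a linear system for
eight ionic volumes. That system is singular: adding any multiple of the
ionic charge vector $(+1,+1,+1,+2,-1,-1,-1,-2)$ to the solution leaves
every electroneutral salt volume unchanged, so the design has rank 7 and
its null space is exactly the charge vector (a property test verifies
this for random stoichiometries). The system is closed with HCl data
plus the literature Marcus polynomial for the hydrated proton,

$$ V_2^0(\mathrm{H}^+, T) = -5.1 - 0.008\,T - 1.7\times10^{-4}\,T^2
 \quad (T\ \text{in °C}), $$

which contributes $-5.41$ cm³/mol at 25 °C. The constraint is handled by
*substitution* (the proton volume is subtracted from the HCl row) rather
than Lagrange multipliers — the estimates are identical and the
covariance bookkeeping trivial.

Two estimation modes are provided, because the study does not fully
specify which produced its ionic table:

* `decompose_at_T()` — weighted least squares (weights $1/SE^2$) on
  per-salt volumes at one temperature; applied to the printed per-salt
  table at 25 °C it reproduces every printed ionic value within
  0.7 cm³/mol (chloride and iodide within ~1 %).
* `global_ionic_fit()` — one grand nonlinear fit of all raw density
  records with per-ion $(V, \alpha, \beta)$ and the proton fixed; this
  is the mode whose uncertainties scale like the published ionic SEs.

On the default synthetic campaign (2040 records — about 2.5× the ~800
measurements of the real study) the grand fit recovers every injected
ionic volume within 2 SE, with SEs of ≈0.10 cm³/mol for monovalent and
≈0.20 cm³/mol for bivalent ions: half the published 0.2/0.4 values, as
expected from the larger synthetic campaign, but with the same 2:1
ratio between bivalent and monovalent uncertainty.

### The curvature contrast

The sign of $\beta_2^0$ separates the ions: negative (concave $V(T)$)
for the anions, predominantly positive for the cations. The study
reports this contrast as significant at $p < 10^{-3}$ without naming the
test; `curvature_contrast()` implements a two-sided z-test on the
difference of inverse-variance-weighted group means (labelled a
reconstruction), with a Welch t-test variant behind a flag. On the
printed ionic coefficients and SEs the z-test gives $p \approx 10^{-11}$.
Note that re-deriving the coefficients through the per-temperature chain
from the printed *per-salt* table (`reproduce_table2()`) yields much
larger $\beta$ uncertainties — propagating printed SEs through five
temperatures without the unprintable correlations is conservative — so
that route alone does not reach $10^{-3}$; the strong significance
belongs to the grand-fit uncertainties.

## Solvation-snapshot analysis

The MD stage consumes ion-centered snapshots (cubic periodic box,
~507 waters, the ion at the center; sulfate uses the sulfur as reference
atom via a per-ion offset). All pair geometry uses the minimum-image
convention, and water internal geometry is unwrapped relative to its
oxygen before any angle is computed.

* **Orientation records**: for each water with ion–O distance
  $d \le 12.5$ Å, the angle $\theta$ at the oxygen vertex between the
  O→ion and O→Q vectors, Q being the midpoint of the two hydrogens.
  (The study's text once says "water center of mass"; the Methods'
  definition — hydrogen midpoint — wins, and `q_mode = "com"` offers
  the alternative.) $\theta \to 180°$ means oxygen toward the ion
  (cation-like first shells), $\theta \approx 60°$ one hydrogen toward
  the ion (anion-like, hydrogen-bond donor geometry).
* **d–θ maps**: 2D histograms, raw or divided by the bin-integrated
  Jacobian $d^2\sin\theta$ and normalized so occupied far-field bins
  average 1. For an ideal-gas generator the corrected map is flat
  (chi-square at $\alpha = 0.01$ in the tests).
* **V(N) curves**: per frame, $V_N = \tfrac43\pi d_{(N)}^3$ with
  $d_{(N)}$ the distance to the N-th nearest water — the simplest
  reading of "the sphere bordering N waters". The fit range starts at
  $N > 35$ (the perturbed shells) and is capped where the mean radius
  reaches half the box edge.
* **Intercept estimator**: a joint linear fit $V = aN + c_\mathrm{ion}$
  with one shared slope across ions (bulk water's molecular volume —
  30.023 ų converts to 18.08 cm³/mol via $N_A \times 10^{-24}$) and
  per-ion intercepts estimating the ionic volumes. (At 20 °C the
  standard conversion of 30.023 ų corresponds to 0.9964 g/cm³, about
  $4\times10^{-4}$ below the 0.9968 quoted alongside it in the
  motivating study; the package documents rather than reproduces that
  inconsistency.)

Because every point of a V(N) curve is computed from the *same* frames,
curve residuals are strongly correlated and ordinary regression SEs are
meaningless. When per-frame curves are retained (the default),
`fit_vn_global()` instead propagates the estimator's linear weights
through the frame-to-frame covariance — frames are independent draws —
giving honest SEs; on hard-core Poisson fluids at $10^4$ frames the
shared slope recovers $1/\rho$ and the intercepts $\tfrac43\pi r_d^3$
within their 95 % intervals.

## What the generators emulate — and what they do not

* `gen_density_dataset()` / `gen_full_study()` reproduce the campaign
  geometry (8-point geometric molality grid — serial dilutions are
  standard practice and the study states only "series of dilutions" —
  3 series, 5 temperatures), the instrument noise and the solvent
  offsets. They do *not* emulate solute–solute interactions, which the
  model itself excludes at these concentrations.
* `gen_solvation_snapshots()` reproduces the marginal (d, θ)
  distributions the estimators consume: uniform/hard-core fluids for
  the null and Poisson references, and Gaussian radial shells with
  von-Mises-like orientation peaks for cation-like (first-shell θ near
  180°), anion-like (θ near 55°) and bulk-like (donor/acceptor mixture
  at θ ≈ 150°/45°) structure. Shell radii, widths and occupancies are
  field-plausible choices (first shells at 2.4 Å / 3.2 Å with 6 / 7
  waters); structured modes exclude uniform background from the
  first-shell region. The generator does *not* model water–water
  hydrogen-bond correlations — a green recovery test establishes that
  the estimators are unbiased for the stated structure, not that TIP3P
  water behaves this way.
* For hard-core reference fluids the per-frame count can be drawn
  Poisson (`count = "poisson"`): with a fixed count the slope of V(N)
  is biased by $n/(n{+}1)$, which a $10^4$-frame fit resolves.

All generators are seed-deterministic (identical seeds give
byte-identical serialized output).

## Numerical choices and degenerate inputs

* Levenberg–Marquardt: analytic Jacobians, $\lambda$ damping by factors
  of 10, relative parameter tolerance $10^{-12}$; identifiability
  failures (single temperature, missing acid rows) are *errors naming
  the offending parameter*, not warnings.
* $m = 0$ is a singularity of the apparent-volume relation (error) but
  a valid input of the closed-form density prediction (returns $d_0'$).
* Linear interpolation of $A_v$ outside the table range, and $d_0(T)$
  outside 0–60 °C, are domain errors.
* `vn_curve()` refuses N beyond what the box can validly contain and
  reports the admissible maximum.
* Rotation is a symmetry of the periodic cell only within the inscribed
  sphere; the invariance tests respect that boundary.

## Known limitations

* Ionic SEs from the printed-table route are conservative (correlations
  between printed per-salt coefficients are unavailable).
* The Mg²⁺ volume inherits the known overestimate relative to
  literature compilations (~5 cm³/mol) that comes from neglecting
  higher-order ion-interaction terms — intentional, since the model
  excludes them at these concentrations.
* No compressibility/speed-of-sound analysis, no higher-order Pitzer
  virial terms, no real-trajectory ingestion beyond the documented XYZ
  and multi-MODEL PDB exchange formats.
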