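---
title: "Monolayer electrostatics: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monolayer electrostatics: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipot)
```

## The problem

Lipid monolayers spread at the air–water interface are the standard model
system for one leaflet of a biological membrane. Two observables organise
their electrostatics:

* the **mean area per lipid** $A$ (Å² per molecule), measuring lateral
  packing, and
* the **dipole potential** $\psi_d$ (mV), the potential drop across the
  hydrated film created by oriented lipid dipoles and interfacial water.

`dipot` turns the raw outputs of a constant-area spreading experiment —
surface pressure $\pi$ versus amount of lipid, and interfacial potential
measurements — into areas per lipid, transverse dipole moments, corrected
dipole potentials, mixture-additivity deviations, and transbilayer
potentials for asymmetric leaflet compositions.

## Saturation-point extraction

In the constant-area method, aliquots of lipid are added to a trough of
fixed area until the pressure stops rising: beyond this *saturation point*
the excess lipid aggregates in the subphase and the monolayer is in
equilibrium with bilayer structures, making it comparable to one bilayer
leaflet. `detect_saturation()` locates the saturation point as the
interception of two least-squares lines, one through the steepest
contiguous window of the $\pi(n)$ curve and one through the plateau.

Algorithmic choices the construction leaves open were fixed as follows:

* **Steepest region**: a sliding window (default 5 points) maximising the
  regression slope, ties broken toward larger amounts. Window width trades
  noise suppression against curvature bias; 5 points works well at the
  default sampling density (40 points per isotherm).
* **Plateau**: all points within 0.5 mN/m of the maximum pressure, but at
  least the three highest-pressure points. The floor matters because with
  measurement noise the raw maximum can be an outlier that would otherwise
  leave fewer than three band members.
* **Preconditions**: the steepest slope must exceed five times the final
  window's slope (otherwise there is no plateau to intercept), and the two
  lines must differ by at least 1° (otherwise the interception is
  numerically meaningless).

The mean area per lipid at saturation follows from
$A_{sat} = S / (N_A \, n_{sat})$ with $S$ the trough area.

## Areas at a reference pressure

Bilayer-equivalent properties are conventionally read at a lateral
pressure of 30 mN/m. `fit_isotherm_polynomial()` describes $\pi(A)$ by a
least-squares polynomial (default degree 3) restricted to areas below
100 Å², the liquid-expanded/condensed region where a low-order polynomial
is adequate; `area_at_pressure()` then inverts the fit. Root selection:
among real roots inside the fitted range, only those on the physically
decreasing branch ($d\pi/dA < 0$) are eligible, and the largest such area
is returned — high-order fits can wiggle, and the largest decreasing-branch
root is the one continuous with the low-pressure data.

## Dipole potentials and dipole moments

The film is modelled as a parallel-plate capacitor of aligned dipoles
(Helmholtz). In the mixed units of the field (mV, mD, Å²):

$$\Delta V = \frac{12 \pi \, \mu_\perp}{A} \qquad \text{(plain)}$$
$$\Delta V = \frac{12 \pi \, \mu_\perp}{A} + \Delta V_0 \qquad \text{(offset)}$$

$\mu_\perp$ is the component of the molecular dipole moment perpendicular
to the interface. It is not measured directly; it is retrieved by
inverting these relations at the saturation point, then used to
re-project the potential to 30 mN/m under the assumption that compression
changes dipole *density* (through $A$) but not orientation. The offset
variant acknowledges the empirical finite intercept of $\Delta V$ versus
$1/A$; intercepts cluster near 100 mV for zwitterionic phospholipids, so
`delta_V0_mV = 100` is the package default for the offset analysis
(configurable). Both variants are always computed side by side
(`mu_eq1_mD`/`psi30_eq1_mV` and `mu_eq2_mD`/`psi30_eq2_mV`), since neither
is uniformly better.

## Charged monolayers: the Gouy–Chapman correction

For films containing ionised lipids the measured potential contains,
besides the dipole term, the diffuse-double-layer surface potential
$\psi_0$:

$$\psi_{measured} = \psi_{dipole} + \psi_0.$$

$\psi_0$ follows from the Grahame equation for an arbitrary electrolyte
mixture,

$$\sigma^2 = 2000\, \varepsilon_0 \varepsilon_r R T \sum_i C_i
\left(e^{-z_i F \psi_0 / R T} - 1\right),$$

with $C_i$ in mol/L and $\sigma$ the surface charge density from the
mole-fraction-weighted formal charge per molecule at the measured area.
`grahame_psi0()` solves this by bracketed root finding on the monotone
signed function $\sigma(\psi_0)$ over ±500 mV (widened once to ±1000 mV,
then an error — double-layer potentials beyond that are unphysical for
these systems), polished to a charge-density residual below
$10^{-10}$ C/m². For a single 1:1 electrolyte the solver agrees with the
closed form $\psi_0 = (2RT/F)\,\mathrm{asinh}\!\left(\sigma /
\sqrt{8000\,\varepsilon_0 \varepsilon_r R T C}\right)$ to under
$10^{-6}$ mV; the test suite also checks it against an independent
bisection solver over a $\sigma \times C$ grid and verifies the relation's
residual for asymmetric multivalent mixtures.

Conventions: $\sigma$ and $\psi_0$ carry sign (negative for anionic
films, so the corrected dipole potential exceeds the measured one);
phosphatidylserine is treated as fully ionised ($z = -1$), the reading
under which the study's own numbers were computed, although partial
ionisation in pure PS films is plausible. The default subphase is 150 mM
NaCl as a 1:1 electrolyte at 298.15 K with $\varepsilon_r = 78.5$ (water,
25 °C; the experiments do not determine $\varepsilon_r$, so the standard
value is used and is configurable). The full buffer
(HEPES/EDTA/azide) is available as an approximate speciation via
`study_subphase(extended = TRUE)`; it shifts $|\psi_0|$ by only a few mV
and is provided for sensitivity analysis, not as the default, because the
minor species' charge states are pH-dependent and not pinned down by the
experiment.

```{r}
sigma <- surface_charge_density(49.4, "POPS")
c(sigma = sigma, psi0 = grahame_psi0(sigma, study_subphase()))
```

One elementary charge per 49.4 Å² is $-0.324$ C/m², giving
$\psi_0 \approx -137$ mV in 150 mM 1:1 salt — the ~135 mV surface-term
magnitude familiar for pure PS films.

## The study records

`study_monolayers()` ships the measured inputs for the eleven
compositions characterised by the constant-area method (pure POPC, POPE,
POPS and sphingomyelin; binary, ternary and quaternary mixtures with
cholesterol; the plasma-membrane leaflet models). `study_dipole_table()`
runs the full analysis on them:

```{r}
study_dipole_table(rounded = TRUE)[, c("composition", "psi_dipole_sat_mV",
                                       "mu_eq1_mD", "psi30_eq1_mV")]
```

One record needs special handling: SPM:CHOL (6:4) has no measured
saturation area, so its dipole moments cannot be recomputed from first
principles. The record is ingested with its reported dipole moments and
30 mN/m potentials as given values, which `analyze_monolayers()` passes
through unchanged. The given values are not mutually consistent to the
last integer (the reported $\mu_\perp$ of 379 mD with the 39 Å² area
yields 366 mV, not the reported 357 mV); the package preserves the
reported numbers rather than silently "fixing" them, and a test verifies
that the cross-system correlation statistic moves by less than 0.02
between the two readings.

Report rounding uses ties-away-from-zero to the nearest integer (the
convention of the source tables; base R rounds ties to even), applied only
at serialisation — all internal arithmetic is full double precision. A
$10^{-9}$ guard absorbs representation error at exact ties.

## Mixtures: additivity and replacement

`predict_additive()` gives the mole-fraction linear combination of pure
values; `predict_replacement()` keeps a reference binary (POPC:CHOL 7:3)
at its measured per-lipid value and substitutes the remaining fraction
with other species' pure values. "Per-lipid value" always counts all
molecules, cholesterol included. Cholesterol's own monolayer was not
measured here; its registry reference values (30 Å², 373 mD) come from
classic monolayer literature. Deviations of observed from predicted
classify each mixture as condensed (cholesterol's well-known effect on
phosphatidylcholine) or expanded (charged PS-containing films).

## Transbilayer potentials

For an asymmetric bilayer, `transbilayer_potential()` differences the
leaflet dipole potentials, inner minus outer — positive for the
plasma-membrane model (SPM:CHOL 6:4 outside, POPC:CHOL:POPE:POPS 4:3:2:1
inside). Two saturation-mode variants are reported: the plain dipole
difference and the difference including each leaflet's $\psi_0$. They
differ for the charged inner leaflet, and the package deliberately
reports both rather than asserting which one a given literature figure
refers to.

## The synthetic generators

Raw spreading isotherms are rarely published, so the generators in
`popc_like_truth()` / `simulate_*()` provide data with known ground truth
for validating every pipeline stage:

* The underlying $\pi(A)$ is a cubic interpolating four anchors placed on
  $\pi = c\,(A^{-2.5} - K)$, through the true saturation point and
  (64.5 Å², 30 mN/m). In amount space this makes the pressure rise with
  mildly *increasing* slope toward the saturation knee — the compression
  geometry the two-line construction assumes, where the steepest window
  sits directly below the plateau. (A curve with slope decreasing toward
  the knee would make "the steepest region" ambiguous under noise and is
  not what constant-area experiments look like.)
* Saturation is a hard clip at $\pi_{sat}$ rather than an asymptotic
  approach, so the knee location — and hence the recovery error — is
  exactly defined.
* Noise is Gaussian and homoscedastic: sd 0.3 mN/m on pressures and 5 mV
  on potentials by default, matching the scatter of the tabulated
  uncertainties (±3 Å² on areas, ±5–15 mV on potentials).
* Seeds are explicit arguments applied locally (`withr::with_seed`);
  generation never touches the global RNG stream, and the same seed and
  parameters reproduce a dataset bit for bit.

What the generators do *not* emulate: compression-cycle hysteresis,
equilibration kinetics, heteroscedastic drift near collapse, and 2D phase
transitions (kinks) within the compression region. Passing the recovery
tests therefore shows the estimators are correct for clean two-regime
isotherms, not that they are robust to every pathology of real traces.

Validation scales used by the test suite: 40-point isotherms, 200 seeds
for saturation recovery (median relative error must stay below 2%, 95th
percentile below 8%) and 500 replicates for dipole-moment unbiasedness.
These sizes give stable quantiles while keeping the suite fast.

```{r}
truth <- popc_like_truth()
iso <- simulate_pressure_amount(truth, seed = 1)
detect_saturation(iso)[, 1:3]
```

## Known limitations

* No Stern layer, ion-specific binding, or curved-geometry
  Poisson–Boltzmann: $\psi_0$ is pure Gouy–Chapman.
* No pKa/speciation engine: formal charges are integers fixed in the
  registry; partial PS ionisation must be emulated by editing the
  registry.
* The offset $\Delta V_0$ is a single global constant, not a per-system
  fitted intercept.
* The two-line construction assumes a sharp saturation; films that
  approach their plateau asymptotically will bias $A_{sat}$ high.
* Interfaces are in-memory tibbles and delimited text; there is no
  instrument I/O.
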