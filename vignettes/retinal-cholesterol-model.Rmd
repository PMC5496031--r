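---
title: "Modelling cholesterol turnover, delivery and drusen dynamics in the outer retina"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cholesterol turnover, delivery and drusen dynamics in the outer retina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retchol)
```

Cholesterol (Ch) in the outer retina is both essential and hazardous: rod
outer segment (ROS) discs are Ch-rich when formed and Ch-poor when
phagocytosed by the retinal pigment epithelium (RPE), while Ch that the RPE
effluxes in large ApoB-containing particles becomes trapped in Bruch's
membrane (BrM) and accumulates as drusen, the hallmark lesion of dry
age-related macular degeneration. This vignette describes the three
steady-state flux models the package implements, the unit and calibration
conventions they rest on, and what the test suite does and does not
establish.

## Units and calendar

All fluxes are areal Ch mass fluxes in pg/mm²/min; the canonical internal
units are pg (mass), mm (length) and min (time). Concentrations cross the
interface in the units the quantities are usually quoted in (mg/dl for
LDL-Ch, µg/ml for ApoA-I) and are converted exactly (`convert_concentration()`).
A permeability P (cm/s) acting on a concentration C (mg/dl) produces the flux
`P * C * 6e6` pg/mm²/min (`permeability_flux()`); the factor is purely
dimensional (600 mm/min per cm/s × 10⁴ pg/mm³ per mg/dl). We fix 1 year =
365 days = 525,600 min and 1 month = 1/12 year = 43,800 min; the sources of
the parameter values do not state a calendar convention, and quantities in
µm/year and months depend on one, so it is pinned here once.

## The parameter registry

Every physical constant lives in a flat registry (`default_registry()`):
name, point value, percent uncertainty, unit, one-line provenance. Scenario
configs are flat YAML files keyed by registry names; unknown keys and
negative values are rejected, and `write_parameters()`/`load_parameters()`
round-trip losslessly. The percent uncertainties are not described in their
sources as SDs, CVs or ranges; we interpret them as coefficients of
variation of a lognormal distribution parameterised by its median
(`sample_parameters()`). The lognormal choice reflects that every quantity is
a positive physical rate or constant; median parameterisation means
Monte-Carlo medians reproduce the point estimates, which the tests verify to
within 5% at n = 2000. `k_t` and `Kin_discs` describe the same measurement
(85 discs/day across 100-disc compartments), so they are perturbed jointly.

## Module 1: the ROS transit chain

The ROS is a chain of `n = 10` compartments of 100 discs. Discs advance with
first-order rate constant `k_t = 0.85`/day (so the mean transit time is
`n/k_t ≈ 11.8` days) and lose Ch with rate constant `k_out` from compartments
2–10; compartment 1 defines the composition of newly formed discs. At steady
state each step multiplies disc Ch by `r = k_t/(k_t + k_out)`, giving a
geometric profile. Two `k_out` conventions are exposed:

* `"calibrated"` (default): `k_out = k_t (6^{1/9} - 1) = 0.1872`/day, which
  makes the compartment-1:10 fold decrease exactly 6 and hence reproduces
  both tabulated turnover anchors (5.84 and 5.84/6 = 0.97 pg/mm²/min)
  simultaneously;
* `"table"`: the rounded printed value 0.19/day, which reproduces them to
  within 2%.

Ch leaving discs enters a recyclable pool; a fraction `f` returns to the rod
inner segment and the rest is taken up by the RPE. Only `f` is identifiable
at steady state — the two pool rate constants it summarises are not — so the
pool has no modelled size, recycling is an instantaneous flux split, and the
external turnover requirement is affine in `f`:

```{r}
p <- load_parameters()
turnover_rate(p$ros, f_recycling = c(0, 0.5, 1))
```

The absolute anchor `j0_flux = 5.84` pg/mm²/min is a primitive parameter
rather than being rebuilt from disc Ch content and rod density, whose inputs
are not part of the registry; this preserves every downstream number.
`simulate_chain()` integrates the time-dependent chain with a stiff-capable
integrator (`deSolve`, lsoda, rtol 1e-10) and converges to the closed form;
the pool compartment in the time course uses an arbitrary documented drainage
constant (24/day) and its transients should not be interpreted, only its
steady-state throughput.

## Module 2: LDL delivery and receptor uptake

LDL crosses the choriocapillaris (CC) endothelium by transcytosis, modelled
as effective permeabilities `P_in = 1.2e-7` cm/s and `P_out = ratio * P_in`
with ratio in 0.1–1, and is taken up by RPE LDL receptors with
Michaelis–Menten kinetics (`Vmax = 13.1` pg/mm²/min, `Km = 5.4` mg/dl,
expressed as LDL-Ch). The BrM free-LDL pool is treated as well mixed with no
binding or degradation — the simplest model consistent with a saturating
uptake curve — so its steady state solves

    P_in C_CC = P_out C_BrM + Vmax C_BrM / (Km + C_BrM),

a quadratic with exactly one positive root, returned in closed form and
cross-checked in the tests against a bracketing root finder. "Maximum flux"
for the 90% criterion means the uptake asymptote `Vmax`, so the 90% BrM level
is `9 Km` and the choroidal threshold follows in closed form:

```{r}
vapply(c(0.1, 0.5, 1), function(r)
  c90_threshold(delivery_params(pout_ratio = r)), numeric(1))
```

These dimensional closed-form thresholds (21.2, 40.7, 65.0 mg/dl) sit 3–12%
below the approximate values usually quoted for this configuration (24, 43,
67 mg/dl); the coupling here is fully determined by dimensional analysis, and
the closed form is authoritative in this package. All thresholds fall below
normal serum LDL-Ch (~100 mg/dl): RPE uptake saturates at modest plasma
levels, which is why the model predicts little sensitivity of retinal Ch
supply to serum LDL.

## Module 3: efflux, drusen growth and clearance

Basal ABCA1 efflux scales the apical delivery constant (6.73 pg/mm²/min) down
by the 6.37:1 apical:basal expression ratio; ApoB-Ch secretion scales the
hepatocyte-equivalent flux (967 pg/mm²/min) by the RPE's relative ApoB (7.5%)
and MTP-A (4%) expression. The resulting small ApoA-I-Ch particles (6.3 nm)
clear through the fenestral pores, and their steady-state BrM concentration
is flux/(P·k) — 0.0014 mg Ch/dl at 1 pg/mm²/min. The Ch:ApoA-I mass ratio
0.14 that converts this to an ApoA-I concentration is a calibrated constant
(consistent with a two-ApoA-I ~6.3 nm particle), not a derived one.

Drusen grow linearly: an ApoB-Ch deposition flux divided by the volumetric Ch
density of the deposit gives a thickness growth rate. The density is
calibrated once from the growth relation itself — 0.7 µm/year at
1 pg/mm²/min implies ρ = 7.51×10⁸ pg/mm³ ≈ 0.75 g/cm³, a physically sensible
bulk lipid density — and the same ρ is then used unchanged for clearance,
which is the internal-consistency argument for the calibration.

Macrophage clearance is `density × vmax_per_cell × s` with
`s = C_ApoAI/(Km + C_ApoAI)` or `s = 1` in the saturating-ApoA-I limit. Both
conventions are exposed; the headline "density required to clear a 120 µm
druse in 10 months" uses the saturating convention (with the baseline factor
25/30 the figure is ~4,260 rather than ~3,550 cells/mm²). Clearance
simulations are clearance-only by default (deposition can be switched on),
matching the way regression is usually simulated:

```{r}
mac <- macrophage_params(density = 1000, saturating_apoai = TRUE)
tr <- drusen_clearance_timecourse(120, mac, p$efflux)
tr$time_to_clear / minutes_per_year()
required_macrophage_density(120, 10 * minutes_per_month(), mac, p$efflux)
```

## The pore-permeation module

`fenestra_permeability()` rationalises the tabulated ApoA-I-Ch permeability
(1.2×10⁻⁴ cm/s) from first principles: Stokes–Einstein diffusivity, the
Renkin centerline hindrance factor
`H(λ) = (1-λ)²(1 − 2.104λ + 2.09λ³ − 0.95λ⁵)` for a particle:pore diameter
ratio λ (with full exclusion at λ ≥ 1), and the open pore area fraction per
unit endothelium. The Renkin approximation is used because it is the
standard closed form for hindered diffusion in cylindrical pores; it is an
interchangeable strategy. The default geometry — 10 nm pores (within the
reported 6–12 nm), 30 nm effective pore length, 14 pores per diaphragm,
3×10⁷ fenestrae/mm² — is a calibration set chosen once to land within the
tabulated value's 41% uncertainty band; the flux model always uses the
tabulated constant, and this module is explanatory. It also demonstrates the
size exclusion that drives the pathology: 21 nm LDL and 70 nm ApoB-Ch
particles have λ > 1 and permeability exactly 0.

## Numerical and design choices

* Closed forms are preferred everywhere a steady state has one (geometric
  chain profile, quadratic BrM balance, linear drusen kinetics); ODE
  integration is used only for time courses and is validated against the
  closed forms to 1e-6 relative in randomized property tests.
* The quadratic's positive root is computed in the numerically safe form
  `(-B + sqrt(B² + 4 b a C Km))/(2b)`, with the `P_out = 0` limit handled
  separately (no steady state once influx reaches `Vmax`).
* Degenerate inputs: `k_out = 0` gives a flat disc profile and zero pool
  efflux; zero macrophage density or zero ApoA-I gives no clearance and an
  undefined (`NA`) clearance time; a zero-height druse clears at time 0.
* Scenario and Monte-Carlo sizes (n = 2000 draws; 101-point grids) are the
  package defaults; medians stabilise well within them.

## What the tests show — and what they do not

The test suite verifies internal consistency (mass balance, round trips,
monotonicity, closed-form-versus-ODE agreement) and that the shipped
registry reproduces the headline steady-state quantities. It does not
validate the parameter values themselves: most were derived from hepatic
lipoprotein data scaled geometrically, or from limited in-vitro RPE data.
The model omits, deliberately: interaction or competition between the
ApoA-I and ApoB efflux pathways; LDLR regulation dynamics (the `Vmax`
already reflects a down-regulated receptor pool); intracellular RPE Ch
pools; macrophage recruitment dynamics; any spatial drusen geometry; and
cone/foveal contributions. Conclusions drawn from the package inherit these
limitations.
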