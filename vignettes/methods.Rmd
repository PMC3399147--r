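---
title: "Methods: a reduced-form vegetation model and its uncertainty analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced-form vegetation model and its uncertainty analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vegens` asks a simple question with many moving parts: when a dynamic
vegetation model projects how plant functional types (PFTs) will be
redistributed across the northern high latitudes over the 21st century, how
much of the spread in those projections comes from uncertain model
parameters, how much from the climate system's response to a given emissions
pathway, and how much from the choice of emissions pathway itself? The
package provides every stage of that analysis — parameter sampling, scenario
generation, simulation, sensitivity statistics, and uncertainty
decomposition — as tested, composable functions. This vignette documents the
model equations, the defaults and why they were chosen, and the boundaries
of what the synthetic setup can and cannot show.

## The simulator

The simulator is deliberately *reduced-form*. It keeps the structural rules
that govern PFT competition in LPJ-class models — Lambert–Beer foliage
cover, bioclimatic gating of establishment and survival, growth-efficiency
mortality, space-limited establishment, and herbaceous-first resolution of
over-full canopies — while replacing the full physiological machinery
(Farquhar photosynthesis, soil hydrology, soil carbon, fire) with a
light-use-efficiency surrogate. The thirteen uncertain parameters enter
exactly where their published descriptions place them; the surrogate's
fixed constants live in one configuration file
(`inst/extdata/pft_defaults.yml`).

Six PFTs compete per grid cell: temperate needleleaved evergreen (TNE),
temperate broadleaved evergreen (TBE), temperate broadleaved summergreen
(TBS), boreal needleleaved evergreen (BNE), boreal summergreen woody (BSW),
and C3 perennial grass (CPG). Each is represented by an average individual
(carbon pools: leaf, sapwood, heartwood, root) and a population density;
grass carries leaf and root pools per unit ground.

**Cover.** An individual's foliage projective cover is
$f = 1 - e^{-k_{beer}\,\mathrm{LAI}}$; a woody PFT's cell cover is
`density x crown area x f`, capped at 1. The sum over PFTs never exceeds 1;
the remainder is bare ground.

**Production.** Gross production uses non-rectangular-hyperbola
colimitation. The light-limited rate is
$J_E = \alpha_{C3} \sum_m \mathrm{APAR}_m f_T(T_m)$, with monthly APAR from
a latitude/season solar-geometry proxy attenuated by cloud cover and scaled
by the PFT's cover; $f_T$ is a 0–1 temperature ramp, gated to the
leaf-on season ($T > 5$°C) for summergreen and grass phenologies. The
capacity-limited rate is $J_C = V_{cap}\, f_{CO_2}(c)\, w$, where
$f_{CO_2}$ is a saturating response normalized to 1 at 370 ppmv, and
$w = \min(1, P\,\mathrm{wue}(c)/D(T_w))$ is an annual water scalar with
demand $D$ rising with warmest-month temperature and water-use efficiency
rising with CO2 — so elevated CO2 acts through both carboxylation and
transpiration, and sustained warming without extra precipitation dries the
cell. GPP is $\alpha_a$ times the smaller root of
$\theta x^2 - (J_E + J_C)x + J_E J_C = 0$; NPP subtracts maintenance
respiration (proportional to live biomass) and growth respiration
($r_{growth}$ per unit NPP), floored at zero. Both CO2 pathways are
monotone, so NPP is non-decreasing in CO2 by construction — a property the
tests assert across random parameter draws.

**Allometry.** Stem carbon converts to a cylindrical stem of diameter $d$
and height $k_{allom2} d^{k_{allom3}}$ through wood density; crown area is
$\min(k_{allom1} d^{k_{rp}}, CA_{max})$; leaf area is capped at
$k_{la:sa}$ times sapwood cross-sectional area. The crown-area power law is
taken on stem *diameter*: with the shipped magnitudes
($k_{allom1} = 100$, $k_{rp} = 1.6$, $CA_{max} = 15$ m²) a height-based
law would pin every crown at the cap for any individual taller than ~0.3 m,
making three of the thirteen parameters inert, whereas the diameter-based
law reaches the cap at $d \approx 0.31$ m — a mature tree — which is both
the standard LPJ formulation and the only reading consistent with those
parameters' substantial published sensitivities.

**Mortality.** The background loss rate is
$k_{mort1}/(1 + k_{mort2}\,\mathrm{greff})$ with greff the year's NPP per
unit leaf area: the asymptotic maximum at zero growth efficiency, declining
toward zero for vigorous growth. Years whose warmest month exceeds a PFT's
heat ceiling add a configured extra rate (0.3 yr⁻¹), and failure of the
20-year-mean survival limits removes the PFT outright. The
establishment step adds `est_max x (1 - woody cover)` saplings per m² per
permitted woody PFT, attenuated linearly to zero as woody cover closes from
0.95 to 1; grass establishment input is proportional to `est_max` so that a
zero establishment rate truly means nothing can colonize. Establishment
never lowers cover and mortality never raises it; the simulator can audit
both claims per step, and the tests require exact zeros.

**Annual loop.** Bioclimatic gating (20-year running means of
coldest-month temperature, warmest-month temperature, and growing
degree-days) → production → allocation/allometry → mortality →
establishment → cover constraints. Runs start from bare ground and spin up
under cyclic replication of the first 30 forcing years (CO2 held at the
first year's value). The default desk-scale spin-up is 200 years, with an
equilibrium diagnostic (relative change of total cover over the final 30
years, flagged against a 10⁻³ tolerance); the full-scale protocol the
package emulates used a thousand years, and desk-scale trajectories that
start near — not exactly at — equilibrium are acceptable for the
sign-level and invariant-level claims tested here.

## Bioclimatic limits

The establishment windows and survival limits are the published LPJ-class
values where such values exist (e.g. BNE establishes for 20-year coldest
months in [−32.5, −2]°C with ≥ 600 growing degree-days and dies back when
the 20-year warmest month exceeds 23°C). Survival floors for the boreal
PFTs are set below the establishment window (−45°C for BNE, −60°C for
BSW) so that the *growing-season* requirement, not winter cold, shapes the
synthetic tree line, matching the dominance of summer warmth in real
high-latitude tree-line position. CPG carries a small degree-day
requirement (50) so that polar desert — not token grass — occupies cells
whose summers never clear 5°C. Under the baseline climatology these limits
produce a plausible zonation: mixed boreal forest to ~70°N, shrubby
summergreen woodland to ~74°N, grass tundra to ~81°N, polar desert beyond;
temperate trees are initially confined to the southern margin and spread
north as the scenarios warm.

## The synthetic climate

No real climate archives ship with the package; the generator emulates the
*statistical structure* the analysis needs, not any particular year's
weather.

- **Baseline climatology.** Zonally symmetric. Annual-mean temperature
  falls with latitude (−0.5°C at 47.5°N to −26.5°C at 87.5°N) and the
  sinusoidal seasonal cycle's amplitude *grows* poleward
  (continentality), capped at 28°C where the Arctic Ocean moderates it.
  This is calibrated against present-day zonal land climate (July ~19°C /
  January ~−20°C near 47°N; July ~15°C / January ~−40°C near 67°N).
  Monthly precipitation declines poleward with a summer peak; cloud
  fraction peaks in winter.
- **Trends.** Each scenario imposes its configured 2001–2100 linear trend
  on the *area-weighted domain-mean* annual temperature and annual
  precipitation — exactly, when noise is off, which is what the trend
  round-trip checks exploit. IGSM-family scenarios multiply the warming
  rate by a latitude factor constructed to have area-weighted mean 1, so
  polar amplification never perturbs the domain trend; IPCC-family warming
  is spatially uniform.
- **Noise.** Interannual variability is a domain-coherent annual anomaly
  plus independent per-cell anomalies. The standard deviations are derived
  from each scenario's published trend R² (σ such that a 100-year OLS fit
  reproduces that R² in expectation), putting the fitted R² in the
  0.85–1.00 range of the source table. Precipitation is clipped at zero
  and cloud at [0, 1] after noise.
- **CO2.** Linear in time between the scenario's 2001 and 2100 endpoints,
  held at the 2001 value before then.
- **Land.** `study_grid()` applies an approximate zonal land fraction
  (continents give way to the Arctic Ocean poleward of ~70°N) so that
  "coverage in km²" integrates over something shaped like the real
  domain. `grid_spec()` builds plain all-land grids for unit testing.

What the generator does *not* emulate — and what passing tests therefore
cannot show — includes spatial covariance of weather, zonal asymmetry
(maritime Europe vs continental Siberia), daily extremes, humidity and
radiation physics, and observed historical sequences. Conclusions from
this package are about the *pipeline* (its statistics, invariants and
qualitative response directions), not about any real landscape.

## Parameter space and sampling

The thirteen parameters are independent uniforms on their published
ranges. The printed range for `k_mort1` is degenerate ([0.01, 0.01]); the
loader repairs it to [0.01, 0.1] — bracketing the standard 0.05 — with a
warning, and the replacement range is an argument. `k_rp`'s standard value
sits on its range boundary; it is accepted as printed.

Latin hypercube sampling follows the classic three-step construction: each
range is split into *n* equal-width strata, one value is drawn uniformly
*within* each stratum (not at midpoints), and columns are paired by
independent uniform permutations with no correlation-reduction
optimization. Strata are half-open `[a, b)` with the last stratum closed,
so occupancy counting is unambiguous; `check_stratification()` verifies
the exactly-one-per-stratum guarantee that distinguishes the design from
i.i.d. sampling.

## Sensitivity statistics

The correlation coefficient, partial correlation and PRCC are implemented
from their defining constructions: PCC is the correlation of the two
residual vectors from regressing $x_j$ and $y$ (each with an intercept —
without one the construction is ill-defined for uncentered ranks) on the
remaining inputs; PRCC applies the same construction to average-ranked
data, which makes it exactly invariant under strictly increasing
transforms. Tests verify agreement with an independent normal-equation
oracle to 10⁻¹⁰. Importance tables sort by |PRCC| with ties broken
positive-first then by input order (cosmetic, but frozen). Per-cell PRCC
maps mask cells where a PFT never appears in any ensemble member — masked
means missing, never zero — and cells with constant response; no
significance testing or multiple-comparison correction is applied because
the analysis reports raw PRCCs only.

## Ensemble summaries and decomposition

Coverage is FPC-weighted spherical cell area (Earth radius 6371 km) — a
continuous km² measure, since the projected trajectories are continuous; a
presence-threshold alternative exists for comparison. Quantile bands use
linear interpolation between order statistics (`quantile` type 7), frozen
in tests. The three uncertainty components follow the scenario design:

- **parameter-induced**: the 10–90% quantile width of the ensemble within
  one scenario (per scenario, and averaged);
- **climate-induced**: within each IGSM emission group, the larger of
  |high − median| and |low − median| of the ensemble *means* — means, so
  that parameter spread is integrated out and the components are not
  double-counted;
- **emission-induced**: |reference-group mean − stabilization-group mean|
  of ensemble means.

The "band width as a fraction of the ensemble mean" diagnostic is reported
per year (band width ÷ that year's ensemble mean); other normalizations
(century-averaged, midpoint-relative) are possible and the choice is
stated here because the verbal definition alone does not fix it.

## Seeds and problem sizes

Every stage derives its seed from one master seed through a fixed affine
map (`derive_seed`), so stages are independently reproducible and the
Latin hypercube draw is unaffected by the scenario list. All seeds stay
below 2³¹. The shipped analysis scripts run at desk scale — 16–200
samples, 34–68 land cells, 80–200 spin-up years — sizes chosen so each
stage completes in minutes while exercising the identical code paths a
full-scale run (1000 samples × 10 scenarios, 0.5° grid, thousand-year
spin-up) would use.

## Known limitations

- The surrogate's absolute productivity and biomass scales are plausible
  but uncalibrated; only structural and directional behaviour is tested.
- One average individual per PFT per cell: no size cohorts, no age
  structure, no explicit light layering beyond the cover constraints.
- Fire, permafrost, nitrogen limitation, land use and migration lags are
  absent, as they are from the model family being emulated.
- The heat-stress mortality magnitude is a configuration constant; the
  emulated model family specifies the mechanism but not the rate.
- Establishment merges saplings into the average individual; cover is
  floored at its pre-establishment value so the documented monotonicity
  holds exactly even when dilution of the average individual would
  otherwise nudge derived cover down by round-off.
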