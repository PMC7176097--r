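---
title: "From incubations to wetland carbon and greenhouse-gas budgets"
author: "wetlandC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From incubations to wetland carbon and greenhouse-gas budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetlandC)
```

## The problem

Shallow deltaic wetlands — coastal salt marshes, brackish lagoons and
restored freshwater wetlands — exchange carbon with the atmosphere through
a handful of measurable metabolisms: photosynthesis and aerobic respiration
of the plankton and the benthos, somatic growth of emergent vegetation, and
net CH~4~ emission from the sediment. Whether a wetland is a carbon sink,
and whether that sink also mitigates warming once CH~4~ is weighted by its
greater warming capacity, is decided by the balance of these terms over a
year and over the surface each process occupies.

`wetlandC` implements that measurement-to-budget chain as a set of small,
composable functions: raw incubation readings in, annual per-site C and
CO~2~-equivalent balances and landscape totals out. A seeded synthetic-data
generator emulates the sampling design so that every stage — and the chain
as a whole — can be tested without field data.

## Oxygen metabolism

Plankton metabolism is measured in paired clear ("light") and darkened
Winkler-type bottles incubated in situ for 2–4 h; benthic metabolism in
clear and dark bell jars staked into the sediment. Each bottle yields a
volumetric rate (mg O~2~ L^-1^ h^-1^, `bottle_rate()`); light bottles
measure net community production (NCP = photosynthesis minus concurrent
respiration), dark bottles respiration (R), and gross primary production is
their sum:

$$\mathrm{GPP} = \mathrm{NCP} + R.$$

The per-replicate chain is:

1. areal normalisation — plankton rates are depth-integrated
   (`plankton_areal()`, rate × 1000 L m^-3^ × depth, assuming a well-mixed
   column, justified by the 0.2–0.5 m depths of the target systems);
   benthic rates scale by the enclosed volume over the jar footprint
   (`benthic_areal()`);
2. replicate aggregation — NCP is the arithmetic mean of the per-bottle
   light rates, R the magnitude of the mean dark rate (`community_rates()`).
   Aggregating per-bottle rates rather than mean concentrations keeps
   bottles with different durations commensurable;
3. stoichiometry — O~2~ converts to C at 12/32 (1 mol O~2~ : 1 mol C,
   `o2_to_carbon()`). Photosynthetic and respiratory quotients are exposed
   as `pq`/`rq` arguments of `oxygen_rates()` and default to 1: GPP and NCP
   divide by PQ, R multiplies by RQ;
4. diel scaling — GPP runs only during daylight (GPP~daily~ = GPP~hourly~ ×
   daylight hours), R is assumed constant over 24 h (`diel_scale()`).

Daytime length is an input of each campaign; where it was not recorded,
`daylight_hours()` supplies the standard solar-declination day length
(non-polar latitudes only, ~0.2 h accuracy).

Two sign conventions deal with measurement noise: net O~2~ *production* in
the dark is physically uninterpretable as aerobic respiration, so R is
clipped to 0 with a warning; a negative *mean* GPP after averaging is
retained but flagged, since discarding it would bias low-production
campaigns upward.

## Vegetation production

Above-ground standing stock is harvested in 15 replicate quadrats of
0.25 m² per campaign. Mean dry weight per m² converts to carbon with a
plant-type coefficient (`carbon_coefficients()`): 0.45 for helophytes
(mainly *Phragmites australis*) and 0.255 for halophytes (*Salicornia*
spp.). Net production between two sampling events is the stock difference
per day (`interval_production()`). Negative differences (senescence,
litterfall) are clipped to 0 by default — observed production is
concentrated in the vegetative period with essentially none in winter, and
decomposition of shed material is not a vegetation *production* term — but
the raw signed rate is always reported alongside, and `clip_negative =
FALSE` reproduces the signed alternative. Uncertainty of an interval is the
sd of the mean stock difference assuming independence between dates.

## Methane

Net CH~4~ emission is measured ex situ: 12 replicate sediment cores per
site and campaign (50 cm × 4 cm methacrylate tubes holding 5–10 cm sediment
and 15–25 cm water under an air headspace) incubated 2–5 days at field
temperature. The headspace accumulation converts to carbon mass by the
ideal gas law at the incubation temperature and 1 atm (`ppm_to_mass_c()`;
CH~4~ dissolved in the enclosed water is ignored, matching what the sensor
sees), and to an areal daily flux by the core cross-section and duration
(`core_flux()`, `site_flux()`).

The response of emission to the two controlling variables uses the two
model families the manipulation experiments identify:

* temperature: $F = a\,e^{bT}$ (`fit_temperature_response()`), fitted to
  the 14/20/25/30 °C factorial design;
* salinity: $F = a\,x^{b}$ on conductivity $x$
  (`fit_salinity_response()`), fitted to the per-site dilution/concentration
  series (1/5×–2× for the saline sites, 1/2×–5× for the freshwater site);
  a declining response has $b < 0$.

Model choice is deliberately *not* automatic: the family is part of the
function contract, not a data-driven selection. Both fits are nonlinear
least squares (Levenberg–Marquardt) initialised from the log-linear
(log–log) regression on the positive fluxes; all points, including
non-positive fluxes, enter the nonlinear refinement. On exact-fit data,
where nls-type machinery fails by construction (zero residuals), the
initialisation already solves the problem and is returned with zero
standard errors. Fit strength is reported as the correlation `r` between
observed and fitted fluxes, with a p-value from the t-transform on n − 2
degrees of freedom; `response_ci_b()` gives a Wald interval for the
exponent, whose empirical 95 % coverage on generator data is ~93 %.

## Annual budgets and GWP

`annual_process_rate()` integrates dated daily rates into g C m^-2^ y^-1^
by period-weighted trapezoid over the sampling dates. A series spanning
less than a year is closed to 365 days by wrapping the last-to-first gap
with the mean of the two endpoint values; a multi-year series (the default
design spans two hydrological cycles) is integrated over its full span and
normalised to 365 days; a single date extrapolates flat. Both variants are
exact on constant series, and agree with a daily-grid oracle within 5 % on
a bi-monthly-sampled seasonal cycle.

`annual_budget()` weights each annual process rate by the surface on which
it operates: plankton and benthos GPP and R, and CH~4~, by the open-water
fraction; vegetation production by the vegetated fraction (which defaults
to complementary coverages). Since the cores are taken in the open-water
compartment, CH~4~ is weighted by the open-water fraction by default;
`ch4_coverage = "total"` exposes the whole-surface alternative. The carbon
balance is the exact sum of the six signed contributions, negative meaning
net capture.

The warming balance converts carbon fluxes to *gas masses* before applying
the CH~4~/CO~2~ factor of 28 (100-year horizon, mass basis):

$$\mathrm{GWP} = (B - F_{\mathrm{CH_4}})\,\tfrac{44}{12}
  + F_{\mathrm{CH_4}}\,\tfrac{16}{12}\times 28,$$

with $B$ the C balance and $F_{\mathrm{CH_4}}$ the (coverage-weighted)
CH~4~-C term, both in g C m^-2^ y^-1^. The mass basis is the accounting
that reproduces the published per-site (B, GWP) pairs to within rounding;
`infer_ch4_from_balance_pair()` is its exact algebraic inverse and turns
any printed pair into the annual CH~4~-C flux it implies — a useful
consistency check when only the balances are published.
`extrapolate_balance()` scales areal balances to wetland-type surfaces
(Tn y^-1^ = g m^-2^ y^-1^ × ha / 100) and `landscape_totals()` sums them
with per-type shares.

Report rounding: balances are meaningful to about 3 significant figures;
the landscape tables carry 2 decimals.

## The synthetic-data generator

`write_fixture_set()` emits a complete input set — campaigns, bottle/jar
incubations, quadrats, cores, site configuration and the generator's truth
— for three archetypes along a salinity gradient (`site_archetype()`):

| archetype | conductivity (mS cm^-1^) | depth (m) | vegetated | plant |
|---|---|---|---|---|
| salt_marsh | 56.6 | 0.45 | 0.37 | halophyte |
| brackish | 31.3 | 0.20 | 0.37 | halophyte |
| freshwater | 2.0 | 0.50 | 0.50 | helophyte |

Conductivities, vegetated coverages and the wetland-type surfaces
(1292.43, 1797.40, 563.06 ha) are the observed site values; depths follow
the reported averages. The brackish vegetated coverage is not reported and
is set equal to the salt marsh's halophyte coverage, as both carry
*Salicornia* meadows. The default campaign structure is 10 roughly
bi-monthly dates over two hydrological cycles (2015/2016–2016/2017), with
sinusoidal water temperature (mean 18 °C, amplitude 10 °C, peak early
August), lognormal conductivity jitter (8 % CV) that keeps the salt marsh
inside its observed 30.3–78.8 mS cm^-1^ range, and day length from the
solar formula at 40.65° N.

True rates are built from baseline values at 18 °C scaled exponentially
with temperature (b = 0.10 °C^-1^ for GPP and R), with a mild power-law
salinity damping of respiration (exponent −0.15); CH~4~ truth is
$5\,e^{0.12T}x^{-0.8}$ mg C m^-2^ d^-1^, which reproduces the observed
orderings (freshwater ≫ salt marsh; summer ≫ winter) and peak magnitudes.
Baselines were chosen once so that the archetypes' annual balances land in
the observed range of tens to hundreds of g C m^-2^ y^-1^ of net capture,
with plankton dominating the brackish site and vegetation the freshwater
site. Vegetation biomass follows a logistic vegetative-season trajectory
with autumn dieback between the archetype's minimum and maximum standing
crop.

Replicate noise is multiplicative lognormal with mean 1 (rates are
positive and right-skewed), CV 0.2 at the bottle/jar/core/quadrat level.
The generator *inverts* the measurement equations with its own inline
arithmetic — true rate to bottle O~2~ difference, to headspace ppm, to
quadrat dry weight — while the pipeline computes forward, so at CV = 0
every stage recovers the truth to numerical precision without the two
sides sharing a code path. One integer seed (expanded into deterministic
per-stage, per-site seeds) fixes every emitted byte.

What the generator does **not** emulate: within-site spatial
heterogeneity (noise is replicate-level only), ebullition and episodic
CH~4~ transport, light limitation or attenuation profiles, tidal or
hydrological forcing of depth and salinity beyond campaign-level jitter,
below-ground production, and lateral carbon exchange. Tests passing on
synthetic data therefore validate the *computation* — unit plumbing,
stoichiometry, integration, weighting — and the statistical behaviour of
the estimators under the stated noise model, not the field realism of any
particular number.

## Numerical choices and degenerate inputs

* Exact-fit (zero-residual) response data bypass the nonlinear refinement,
  as described above; constant flux yields b = 0 with r defined through
  the residual sum of squares.
* Zero-conductivity points are excluded from the salinity fit with a
  warning rather than shifted, since any offset choice would be arbitrary.
* `annual_process_rate()` rejects unsorted or duplicate dates rather than
  silently reordering.
* Degenerate geometry (non-positive headspace, jar footprint, depth,
  duration, daylight outside [0, 24]) errors early with a named message.
* The trapezoid year-wrap uses the mean of the endpoint values; for the
  default two-cycle design the span-normalised branch applies instead, so
  the choice only matters for single-cycle subsets.

## Problem sizes

The shipped tests run the full three-archetype pipeline (10 campaigns,
4 + 4 bottles and jars, 12 cores, 15 quadrats per site and campaign) in a
few seconds, and the parameter-recovery study uses 100 simulated
experiments per response family (4 levels × 5 replicate cores each) —
sizes chosen to match the field design while keeping a complete run
interactive.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile()
paths <- write_fixture_set(dir, generator_config(seed = 1))
camp <- read_campaigns(paths[["campaigns"]])
rates <- dplyr::bind_rows(
  oxygen_rates(read_incubations(paths[["oxygen_incubations"]]), camp),
  vegetation_rates(read_quadrats(paths[["quadrats"]])),
  site_flux(read_cores(paths[["cores"]]))
)
sites <- read_sites(paths[["sites"]])
budgets <- site_budgets(rates, sites)
landscape_extrapolation(budgets, sites)
```

All three archetypes come out as annual C sinks (negative balances) with
net mitigation (negative GWP), the freshwater site's vegetation term being
its dominant sink — the qualitative pattern the budget method is built to
resolve.
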