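---
title: "Methods: harmonizing and analyzing the Arctic surface energy budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonizing and analyzing the Arctic surface energy budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcticseb)
```

## The model and its assumptions

At the land surface the energy budget (SEB) balances net radiation against
the turbulent and conductive heat fluxes,

$$R_{net} = SW_{net} + LW_{net} = H + LE + G + M,$$

with net shortwave $SW_{net} = SW_{in} - SW_{out}$, net longwave
$LW_{net} = LW_{in} - LW_{out}$, sensible ($H$), latent ($LE$) and ground
($G$) heat fluxes in W m⁻², all heat fluxes positive away from the surface.
The latent heat of fusion $M$ (snowmelt) is carried in the identity for
completeness but never computed by this package. Albedo and surface
temperature tie into the radiative budget through

$$R_{net} = SW_{in}(1 - \alpha) + LW_{in} - \varepsilon\,\sigma\,T_{surf}^4,$$

with emissivity $\varepsilon \approx 1$; the package uses this second
identity as a *validation property* of its synthetic data and harmonization
chain, not as an estimator.

The analysis questions the package answers are: (1) which site-level
drivers best predict summer (June–August) flux magnitudes across a
multi-network site archive; (2) how large the per-vegetation-type flux
magnitudes are, accounting for network-level grouping; (3) how flux
seasonality ("summer-regime" timing) relates to snow phenology.

## Harmonization rules

Sub-daily records (half-hourly or hourly, local standard time) pass
through fixed quality rules: gap-filled records are discarded; shortwave
and longwave radiation values above 1400 W m⁻² and negative
incoming/outgoing radiation components are removed; albedo outside
$[0, 1]$ and temperatures below −100 °C are removed. Turbulent fluxes are
*not* sign-filtered — negative $H$ over cold surfaces is physical. Daily
means/minima/maxima are computed only for days with at least 65% of the
nominal slots present and no internal gap longer than 4.8 h. Numerical
choices made where the rules admit interpretation:

* the completeness denominator is the *nominal* day (48 half-hourly or 24
  hourly slots), and the day boundary closes missing runs;
* both thresholds are inclusive (≥ 65%, ≤ 4.8 h);
* replicated sensors are averaged within each network first, then daily
  values are averaged across networks keyed on (site, date, variable);
* daily albedo is the ratio of daily-mean reflected to incoming shortwave
  (energy-weighted), not the mean of instantaneous ratios, and is defined
  only when daily-mean $SW_{in} \ge 10$ W m⁻² — instantaneous ratios blow
  up at low sun, and the energy-weighted form is the one that preserves
  the radiative identity above;
* a directly measured $R_{net}$ always wins over the component-derived
  value; missing entries are filled from components;
* surface temperature can optionally be inverted from $LW_{out}$ with
  $\varepsilon = 1$; this is off by default because $T_{surf}$ is normally
  observed.

## Potential-shortwave normalization

Normalized fluxes are daily values expressed as a percentage of the day's
maximum potential incoming shortwave radiation,
$n.X = 100\,X / S_{pot}^{max}$. We interpret the potential as
top-of-atmosphere horizontal irradiance at the day's minimum solar zenith:
$S_{pot}^{max} = S_0 \, E_0(d) \cos z_{min}$ with $S_0 = 1361$ W m⁻² and
the Spencer series for declination and eccentricity. Terrain shading and
atmospheric transmission are deliberately ignored: the normalization only
needs a consistent seasonal–latitudinal scale, and a terrain model would
add inputs the rest of the analysis never uses. Normalized values are
undefined when $S_{pot}^{max} < 1$ W m⁻² (polar-night guard), and
normalization happens on daily values *before* any seasonal averaging.

## The 15 SEB drivers

Five categorical drivers (vegetation type, landscape-scale CAVM type,
CAVM bioclimatic subzone, permafrost extent, permafrost ground-ice class)
and five numeric drivers (cloud cover, cloud-top temperature, latitude,
altitude — plus mean annual temperature) are consumed as site metadata;
the remaining drivers are computed from per-site series:

* **Continentality** (Conrad): $1.7\,(T_{max} - T_{min}) /
  \sin(\varphi + 10^\circ) - 14$ from monthly temperature extremes. The
  sine is evaluated in degrees — the classical form — because a
  radians-valued latitude plus the constant 10 is dimensionally
  incoherent; a flag restores the literal radians reading for comparison.
* **Summer warmth index**: annual sum of monthly means above 0 °C.
* **Snow amount**: annual precipitation on days with mean air temperature
  ≤ 0 °C (inclusive threshold).
* **Snow duration**: per-year difference between the autumn snow-onset
  date and the spring snow-free date, each defined as the mean day of year
  of the last day in the old category and the first day in the new one;
  the per-site driver is the median across years. Transient midsummer
  snow is handled by searching spring transitions in DOY 1–212 (taking
  the last) and autumn transitions in DOY 182–366 (taking the first).

Multi-year inputs average the per-year index values.

## Variance partitioning

Site-level seasonal means (site-years require ≥ 80% daily coverage of the
season; sites average their qualifying years) are regressed on every
unordered pair of the 15 drivers — 105 pairs, evaluated in both predictor
orders, across 14 responses (8 measured/derived plus 6 normalized fluxes),
i.e. 2940 ordered model evaluations. For a pair $(A, B)$:
$\mathrm{first}(A) = 100\,R^2(A)$,
$\mathrm{last}(A) = 100\,[R^2(A,B) - R^2(B)]$, and the reported share is
their mean — for two predictors this *is* the LMG/dominance decomposition.
Plain (not adjusted) $R^2$ is used, matching a "% variance explained"
reading; adjusted $R^2$ can be negative and breaks the additivity
identities that the tests verify ($\mathrm{first}(A) + \mathrm{last}(B) =
100\,R^2(A,B)$). Categorical drivers enter as full dummy blocks, so a
block's share is its joint contribution. Negative last-shares (possible
under suppression) are kept internally and floored at zero only in the
reported averages. Sites missing a driver are dropped listwise per pair,
maximizing each model's n. Pairs whose design is aliased or leaves fewer
than three observations above the coefficient count are skipped with a
warning rather than fitted badly.

## Magnitudes

Per-type seasonal magnitudes come from a linear mixed model — vegetation
type fixed, data-distribution network a random intercept — fitted by REML,
with estimated marginal means ± 95% CI and a type-III F test. Denominator
degrees of freedom use the Satterthwaite approximation by default and are
configurable; published tables of this kind show software-specific (even
negative) denominator df that no reimplementation can reproduce exactly,
so F and p are validated on equivalence cases instead: with a single
network the model collapses to one-way ANOVA on site means, and the
per-type estimates equal ordinary means of site means (tested to 1e-6).
Post-hoc pairwise contrasts multiply raw p-values by the number of
comparisons (Bonferroni, capped at 1). The omnibus effect is flagged "not
shown" when three or more of the seven canonical classes are absent.
Summer Bowen ratios are $H/LE$ from the per-type estimates; a zero-LE
denominator with negative $H$ is displayed as "<0" rather than forced to a
number.

## Seasonality

Per-type DOY climatologies average each site's daily values across years,
then sites within a type (mean ± s.e.). Feb 29 is dropped before DOY
indexing so all years share a 365-day axis. Smoothing is a centered
15-day moving average that wraps across the year boundary (the annual
cycle is periodic); windows with fewer than 8 of 15 days present yield
missing values. The summer regime of a smoothed curve is the *longest
contiguous run* of days above 0 (W m⁻² for fluxes, °C for surface
temperature) or, for albedo, below the midpoint of the smoothed curve's
annual minimum and maximum — the longest-run rule is robust to brief
noise-driven sign flips in the shoulder seasons and coincides with the
first/last crossing on smooth unimodal curves (tested). The albedo
extremes are taken from the smoothed curve because raw daily extremes are
noise-dominated. Latent heat flux is excluded from regime detection (it
is positive essentially year-round). Regime offsets are computed at the
vegetation-type level — site-level seasonality is not resolvable with the
data coverage this design mirrors — against type-level snow dates
(per-site medians over 2000–2020, averaged across the type's sites), and
start/end offsets across types are compared with two-sample Welch t-tests
(Satterthwaite df).

## The synthetic network: what it emulates, and what it does not

The generator reproduces the *statistical structure* the analysis chain
assumes: seven land-cover classes (the five main CAVM physiognomies plus
boreal peat bog and glacier), several sites per class at class-specific
latitudes, multiple distribution networks with a fraction of sites
duplicated across two networks with small sensor offsets, replicated
sensors, gap-filled flags, out-of-range outliers (e.g. radiation above
the 1400 W m⁻² filter bound, so the filter's effect is observable), and
contiguous gaps with a configurable mean length that stress the 4.8 h
rule.

Non-shortwave variables follow cosine annual cycles in DOY with additive
Gaussian noise; cosines keep closed-form seasonal means available as
oracles for recovery tests. Cycle levels and amplitudes are solved so the
JJA and winter means hit per-type anchors chosen from the magnitudes
reported for circumpolar flux networks; in particular the summer $H$ and
$LE$ anchors give the canonical Bowen-ratio ordering (boreal peat bog
lowest, shrub tundra highest among vegetated classes, barren and glacier
negative). Incoming shortwave follows true solar geometry (zero below the
horizon) times a bulk transmissivity of 0.65; reflected shortwave applies
a snow-dependent albedo transitioning logistically (≈ 1 week) around each
site-year's snow dates between a snow value of 0.8 (glacier 0.75) and a
per-type summer value. Surface temperature is generated by inverting the
longwave-out cycle through the Stefan–Boltzmann law so the radiative
identity holds exactly on noise-free data.

The generator does **not** model cloud variability, advection, spatial
correlation between sites, diurnal cycles of the non-radiative fluxes, or
any land-surface physics. Passing tests therefore demonstrate that the
*pipeline* is correct (rules applied exactly, estimators recover known
generating parameters), not that the synthetic world reproduces real
Arctic observations. Quantities that depend on the real archive — actual
explained-variance percentages, magnitude tables, offset values — are
checked as *properties* (orderings, recovery within noise-scaled
tolerances, calibration of test sizes), not as numeric reproductions.

## Problem sizes and defaults

The default study configuration runs 2 sites per class over 3 years at
hourly resolution (≈ 4.7 million sub-daily records), a scale chosen so
the full chain — generation, harmonization, drivers, variance
partitioning, magnitudes, seasonality — completes in minutes on one CPU
while leaving every structural feature (networks, replicates, gaps,
outliers) active. Driver-importance recovery experiments use site-level
simulated driver tables (35 sites, vegetation-type variance dominance 16×
per competing driver, noise s.d. 1) with 100 replicates; Welch
calibration uses 10⁴ null replicates at n = 5 per group with a 3:1
standard-deviation ratio.

## Known limitations

* The potential-shortwave normalization ignores terrain, so normalized
  values are comparable across sites only up to topographic effects.
* The mixed model treats network as a random intercept with typically few
  levels; variance-component estimates are then weakly identified
  (singular fits are possible and harmless for the marginal means).
* Regime detection needs a curve that actually crosses its threshold;
  always-positive or always-negative curves return the full year or a
  missing regime, respectively, and downstream aggregation skips missing
  regimes.
* The variance-partitioning scheme is restricted to two-predictor models
  by design; it quantifies pairwise confounding, not a full joint
  decomposition over all 15 drivers.
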