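---
title: "Model and methods behind foodshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind foodshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`foodshift` is a deliberately stylized, desk-scale partial-equilibrium model
of the global food system, built to analyse scenarios in which beef,
chicken, pork and milk are progressively substituted by plant-based
alternatives defined through ingredient-share recipes.  This vignette is the
package's own account of the model: its structure and assumptions, the
parameters that matter, what the synthetic-data generator does and does not
emulate, the numerical choices, and the known limitations.  Large
global land-use models resolve gridded yields, dozens of economic regions
and detailed livestock systems; `foodshift` keeps the same skeleton —
welfare maximization, endogenous prices, recursive decadal dynamics,
recipe-based substitution, land/GHG/nitrogen/biodiversity/food-security
accounting — at a size where every component can be verified against closed
forms and brute-force oracles.  Only directional and structural conclusions
are claimed, never the calibrated magnitudes of a full-scale model.

## The market equilibrium

Each decadal step solves one market instance.  For region $r$ and commodity
$i$ (18 crops, 7 animal products, 13 macro regions), food demand has linear
inverse demand $p = a_{ri} - b_{ri} q_{ri}$ and supply has linear marginal
cost $c_{ri} + d_{ri} x_{ri}$.  The solver maximizes the sum of consumer and
producer surpluses minus trade and land-conversion costs,

$$W=\sum_{r,i}\Big(a q - \tfrac{b}{2}q^2\Big)
  -\sum_{r,i}\Big(c x + \tfrac{d}{2}x^2\Big)
  -\sum_{r,i}\big(\tau^{imp} m + \tau^{exp} e\big)
  -\tfrac{\varepsilon_t}{2}\sum (m^2+e^2)
  -\sum_{r,k}\big(\kappa_k c_k + \tfrac{\varepsilon_c}{2}c_k^2\big),$$

subject to:

* **Market clearing** per (region, commodity):
  $x + m - e - q - \text{feed}(x_{\text{livestock}}) -
  \text{alt}_{\text{ingredient}} = 0$.  Feed demand is an intermediate-use
  block: livestock output times system feed-conversion ratios, spread over a
  fixed feed basket (maize, soybean, wheat, barley, sorghum, cassava).
* **World pool trade**: imports $m$ and exports $e$ clear a single world
  pool per commodity.  This is equivalent to bilateral origin–destination
  flows whose unit cost separates as
  $\tau_{od} = \tau_o^{exp} + \tau_d^{imp}$; we chose it over explicit
  bilateral flows because it keeps the quadratic program dense-solvable at
  13×25 markets while supporting exactly the constraint the scenarios need —
  a cap on total imports across a macro-region border.  A small quadratic
  trade term $\varepsilon_t$ makes flows unique and the objective strictly
  concave.
* **Land balances**: cropland use $\sum x/\text{yield}$ and grassland use
  $\sum g_{ra}\, x_a$ must fit within endowments plus conversions.  Five
  conversion activities per region — natural→cropland, natural→grassland,
  grassland→cropland, abandoned→cropland, abandoned→grassland — carry
  annualized costs (defaults 70/35/20/10/5 USD ha⁻¹ yr⁻¹).  Conversion of
  natural land is one-way and recorded as deforestation (split between
  forest and other natural land in proportion to remaining stocks);
  agricultural land no longer used is abandoned.  The abandoned class is
  cheap to re-convert and nearly carbon-neutral to reuse: without it, land
  freed in one decade would be structurally lost to agriculture and regions
  with growing food demand would keep deforesting even while idle farmland
  sat next door — exactly the artefact the cheap-reuse class removes.
* **Scenario blocks**: exogenous substitution wedges (below), import caps
  under local sourcing, and the alternative-ingredient crop demand.

Prices are reported as the duals of the clearing constraints.  For every
commodity with endogenous demand the dual equals the inverse demand at the
consumed quantity (the tests verify this).  For ASF products whose food
demand is fixed by a substitution wedge, the dual is the supply-side
marginal value — the economically meaningful market price, which falls as
substitution deepens; the inverse demand evaluated at the restricted
quantity would instead measure consumers' willingness to pay and rise, which
is not what a food-price indicator should report.

**Livestock extensification.**  Ruminant productivity responds to grassland
rents with multiplier $\phi = \mathrm{clamp}\big((P_L/P_{ref})^{\eta}\big)$,
$\eta = 0.2$, clamp $[0.7, 1.15]$, applied recursively (each step uses the
previous step's shadow rent).  Cheap land therefore raises per-unit
grassland use and enteric emission intensity, the rebound that erodes part
of the benefit at high substitution levels.  Because shadow rents are zero
whenever a land constraint is slack, the rent entering the response is
`rent_floor + shadow price` with a 100 USD/ha floor, so the ratio is always
defined.

## The substitution scenarios

A scenario is one point in a six-dimension grid: scope (global or one of the
13 regions), products (one of beef/chicken/pork/milk, or all four), recipe
rule (a fixed recipe, or least-cost endogenous choice — the latter only when
all products are substituted), level $s \in \{0.10, 0.25, 0.50, 0.90\}$,
sourcing (global, or local with crop imports capped at their REF level on
the macro-region border) and processing (inefficient: the full primary crop
behind each processed ingredient is charged; efficient: only the ingredient
mass itself).

The substituted fraction ramps linearly with anchors $f(2020)=0$ and
$f(2050)=s$, evaluated on the decadal grid, so the first non-zero step is
2030 ($f = s/3$) — this reconciles a ramp that "starts in 2030" with one
that is "linear after 2020" on a decadal grid, the one place where the two
natural readings of the design had to be merged.  In scope, ASF food demand
is fixed *exactly* at $(1-f)$ times its REF value through equality rows in
the QP (not an upper bound), and an equal product mass of alternatives is
created with the same regional calorie content — so conservation of REF ASF
calories holds by construction, to solver precision.  Out-of-scope regions
keep fully endogenous demand; the rebound effect (their consumption rising
as world prices fall) is an output, not an input.  Feed and other
intermediate uses of ASF commodities are never capped directly.

Endogenous recipe choice minimizes the primary-crop basket cost per tonne of
alternative at the current step's prices.  Since those prices are only known
after the solve, the choice uses the previous step's scenario prices (base
prices at 2020) — consistent with the recursive-dynamic structure.  Ties
break lexicographically by recipe id.

## Recipes and nutrition

The eleven recipes (five beef, two each for chicken, pork, milk) are shipped
as a packaged CSV of ingredient mass shares with protein/binder/oil roles.
The non-itemized remainder is water, contributing neither nutrients nor crop
demand; meat recipes leave roughly 48–62% water and milk recipes 88%, and
the tests assert these bands.  Each recipe's vegetable oil is assigned per
region: the most abundant oil by production plus imports (global sourcing)
or by local production alone (local sourcing), constant over the run, with
all six oils treated as functionally interchangeable.

Protein quality uses the Amino Acid Score: the minimum, over nine essential
amino acids (sulphur and aromatic acids scored as groups), of the ratio of
the recipe's pooled amino-acid content per gram of protein to an adult
scoring pattern, truncated at 1.0 and not corrected for digestibility.  The
packaged ingredient nutrient and amino-acid profiles are synthetic fixtures
in nutritionally plausible ranges — all numeric tests on them use internal
oracles (hand-computed weighted sums), not external reference values.  With
these fixtures every recipe reaches an AAS ≥ 0.9 except M2
(rapeseed-meal/wheat-gluten milk), which is lysine-limited and passes the
equivalence check only through its documented supplementation exemption.
Macronutrient parity with the replaced product is checked with default
absolute tolerances of 0.05 for protein and fat and 0.15 for carbohydrate —
looser for carbohydrate because binder ingredients necessarily add
carbohydrates that lean animal products lack.

Ingredient-to-primary-crop conversion yields (isolates ~0.25–0.35, flours
~0.6–0.8, oil extraction 0.15–0.42) are likewise packaged fixtures chosen
from plausible processing ranges.

## The synthetic world generator

`generate_world(config, seed)` is deterministic in `(config, seed)` and
emulates the structural conditions the analysis assumes:

* 13 macro regions with population and income-per-capita trajectories that
  grow monotonically to 2050 with decelerating decadal growth rates
  (convergence-style dynamics); regional archetypes put 2020 population at
  7.5 billion and incomes between 1.6 and 63 thousand USD.
* Per-capita diets that scale with income (total dietary energy from ~2200
  to ~3400 kcal/person/day, ASF share from ~13% to ~29%), split across
  commodities by archetype shares with log-normal regional heterogeneity
  (`noise_sd`, default 0.15, is the single amplitude knob).
* Demand curves calibrated through archetype prices and price elasticities
  (0.3 crops, 0.5 ASF), supply curves with elasticity 1.2 (which keeps all
  marginal-cost intercepts non-negative), yields, feed conversion and
  grassland requirements that put base-year cropland near 930 Mha and
  grassland near 2100 Mha.  Technological trends: crop yields +6% per
  decade, ruminant productivity +8% per decade, supply-cost decline 3% per
  decade.  Land-scarce regions (India) are fitted by raising yields and
  intensifying ruminant systems until the base-year footprint fits inside
  the region — the generator's guarantee that the 2020 state is feasible.
* The 2020 state is an actual solved equilibrium; agricultural endowments
  are then tightened to the solved land use so the base year starts with
  neither slack nor spurious abandonment.

Under these defaults the reference scenario reproduces the qualitative
baseline the analysis needs: ASF consumption +42% by 2050, continued
conversion of natural land (~200 Mha over three decades), crop prices
drifting down a few per cent, declining biodiversity intactness and a
prevalence of undernourishment falling from ~15% to ~7%.

What the generator does **not** emulate: real trade patterns and bilateral
frictions, within-region heterogeneity (each macro region is one
representative consumer and producer), cross-price demand terms, climate
impacts on yields (the world assumes a constant climate), storage and
inter-annual variability, and any calibration to observed statistics.
Passing tests therefore demonstrate internal consistency and the directions
and rough proportions of responses — not predictions for the real world.

## Environmental and food-security accounting

* **Non-CO2 agriculture**: enteric CH4 (t CH4 per t product, divided by the
  intensity multiplier and the productivity trend), manure-management CH4
  and N2O, N2O from excretion on pasture, soil N2O proportional to total
  cropland nitrogen input, rice CH4 per hectare.  GWP100 defaults are the
  AR5 values (CH4 28, N2O 265) and are configurable, since CO2-equivalent
  magnitudes depend on this choice.
* **Land-use-change CO2**: stock differences (forest 150/100/80 t C/ha by
  climate zone, other natural 40, grassland 10, cropland 5, abandoned 10)
  released linearly over the decade of conversion.  Abandonment itself is
  carbon-neutral: regrowth is credited only through explicit restoration.
* **Restoration**: of each decade's newly abandoned area, the region's
  `forest_biome_share` is eligible for afforestation (clamped to per-region
  min/max bounds, defaults 0 and unbounded); the rest stays in the abandoned
  pool with no credit, reusable by agriculture.  Cohorts accrue carbon along
  $C(\tau) = C_{max}(1 - e^{-k\tau})$ with $C_{max}$ equal to the mature
  forest density of the zone and $k$ anchored so tropical stands recover
  about 40% of mature density in 20 years (0.026 yr⁻¹; temperate 0.020,
  boreal 0.012) — saturating-exponential regrowth in the range reported for
  secondary-forest chronosequences.  The sink attributed to a report year is
  the forward decadal increment $[C(\tau+\Delta)-C(\tau)]/\Delta$ per
  cohort.
* **BII**: area-weighted intactness coefficients (cropland 0.40, grassland
  0.55, forest 0.95, other natural and abandoned 0.70, primary 1.0);
  restored cohorts recover linearly from the abandoned coefficient to a
  secondary-forest ceiling of 0.95 over 60 years.  The coefficients are
  synthetic stand-ins in the published range of land-use intactness
  estimates; only directional BII claims are made.
* **Food security**: regional dietary energy availability is computed from
  equilibrium food calories (alternatives count toward calories;
  their prices are excluded from the Paasche indices).  Undernourishment is
  the log-normal tail below the minimum dietary energy requirement, with
  $\sigma^2 = \ln(1+CV^2)$ and $\mu = \ln DEC - \sigma^2/2$; high-income
  regions are assigned zero risk.  The MDER is a demographic-weighted mean
  over child/adult/elderly requirements with slowly aging shares.  The CV
  declines with cumulative income growth — the gap above the floor of 0.2
  shrinks by 0.02 per 10% income gain, a configurable rate chosen because
  the direction and the floor are specified by the modelling tradition but
  the historical rate is not; income declines do not worsen it.

## Numerical choices

* Quadratic program solved by `quadprog::solve.QP` (dual active set).  The
  diagonal Hessian is floored at $10^{-6}$ for strict convexity (far below
  any model-scale coefficient).  Inequality rows receive a $5\times10^{-7}$
  slack — equalities stay exact — because degenerate vertices (several
  resources exhausted simultaneously) otherwise make the active-set method
  report false infeasibility; the slack escalates once to $10^{-4}$ before
  an instance is reported infeasible.  Solutions are clamped to the
  non-negative orthant and dust below $10^{-9}$ (quantities) or $10^{-6}$
  Mha (land flows) is zeroed.
* Market-clearing equalities hold to machine precision; the tests enforce
  $10^{-6}$ relative.  Welfare is recomputed from the clamped solution.
* Ties in recipe selection break lexicographically; the substitution level 0
  is allowed and reproduces REF bit-for-bit because the wedge machinery is
  skipped entirely when $f = 0$.
* Degenerate inputs: empty product sets, unknown regions, non-decadal year
  grids, min > max restoration bounds, zero-protein recipes, zero NUE and
  zero Paasche denominators all raise typed configuration/domain/accounting
  errors rather than propagating NaNs.

## Problem sizes

The default world solves a QP with 1365 variables and ~1800 constraints per
step (about 5 s each); a full four-step scenario run takes ~25 s on one
CPU.  The test suite uses 2- and 3-region worlds (≈ 300 variables, well
under a second per solve) for unit and property tests, and the default
13-region world for the scenario-grid acceptance properties; the brute-force
welfare oracle runs on 2-region, 1-commodity instances at 0.01 grid
resolution.  These sizes were chosen so the whole suite, including five full
scenario runs, completes in a few minutes.

## Known limitations

Beyond the generator's idealizations listed above: demand is independent
across commodities (no cross-price or substitution-in-consumption terms, so
eggs and other meat respond to substitution only through supply-side and
land-market channels); processing by-products either vanish or fully find a
use (the two poles, with reality somewhere between); restoration bounds
default to unbounded maxima; manure nitrogen and total nitrogen input are
separate accounts rather than a closed nitrogen cycle; and the
welfare-theoretic interpretation of fixed demand wedges (forced substitution
has no utility representation) is the standard caveat of exogenous-diet
scenario analysis.
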