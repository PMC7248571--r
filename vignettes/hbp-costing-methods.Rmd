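---
title: "Methods: counterfactual costing of essential health-benefits packages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual costing of essential health-benefits packages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbpcost)
```

## The question the model answers

Given a registry of essential health interventions — each with a unit cost
from some costing study, a population in need, and a baseline coverage in two
stylised country income groups — what would it cost *per year* to deliver the
whole package at a counterfactual target coverage, and how does that cost
decompose? The model is deliberately static: it prices one steady-state year
(2015 epidemiology, 2016 US dollars), not a scale-up trajectory, and it works
on stylised aggregate country groups, not specific national health systems.
Annualised long-run average costs stand in for marginal costs because the
modelled expansion is large relative to baseline; economies of scale or scope
are not modelled.

## Cost standardisation

Raw study costs arrive in some currency, price year, and setting. Three
composable scalar operations standardise them, in this order:

1. `to_usd_2016()` — exchange-rate conversion and inflation to a 2016 USD
   base: `value × fx(currency, year) / index(year)` with `index(2016) = 1`.
   Exchange-rate rather than PPP dollars keep the national-payer perspective:
   internationally traded inputs really are bought at market exchange rates.
2. `transfer_unit_cost()` — setting transfer. The traded fraction `τ` of the
   cost is left unchanged; the non-traded remainder (dominated by health
   worker salaries) scales with the ratio of target to source GNI per capita:
   `c × [τ + (1 − τ) · target/source]`. The operation is linear in cost and
   monotone in target GNI whenever `τ < 1`, and it commutes with
   annualisation — both are scalar multipliers, a property the tests check.
3. `annualize()` — per-episode costs (acute care) are converted to
   per-beneficiary-year by the expected episode rate; per-patient-year costs
   (chronic care) pass through.

**Bundled price index.** The shipped `indices.csv` is a *synthetic stand-in*:
a US-GDP-deflator-style series at a constant 2% per year over 1990–2016, USD
only. Real analyses should supply their own series via
`default_price_index(path)`. No re-adjustment is made for the discount rates
of the source studies — without their primary data that correction is not
identifiable.

**Default traded fraction.** When a registry row leaves `traded_fraction`
blank, the CLI fills in 0.30 (`default_traded_fraction` in the config): a
middle-ground for drug/commodity-heavy interventions. It is a configuration
default, not a constant, because the appropriate value is
intervention-specific.

## The costing engine

Coverage is interpreted as the fraction of the *population in need* reached
(not of the whole population); the glossary term "80% population coverage"
is ambiguous on this point, and the population-in-need reading keeps the
arithmetic consistent for interventions whose eligible population is small.

With baseline coverage `b` and target `t = 0.80`:
`baseline = u·N·b`, `total = u·N·max(b, t)`, `incremental = total − baseline`.
The `max` is the default clamping rule: an intervention already above target
is *maintained*, not cut back — negative "savings" from withdrawing care are
not a policy the model should silently recommend. Setting
`coverage_policy(clamp_negative_increments = FALSE)` prices exactly the
target instead, for exploratory use. Clamping gives the engine its
monotonicity properties (incremental cost is non-decreasing in `t`,
non-increasing in `b`), which are property-tested.

**De-duplication and markups.** Interventions intentionally appear in several
of the 21 essential packages. Per-package totals count them in every package
they belong to (a package share then reads as "the cost that would remain if
all other packages were removed"), while package-set totals count each
intervention once. Health-system costs — facility-level (rent, utilities,
maintenance) and above-facility (supply chain, financing, information
systems, administration), with in-service training assumed inside — are
proportional markups applied to *de-duplicated* totals only, never per
intervention, so package-level rows report pure service-delivery cost. The
defaults `facility = 0.45`, `above_facility = 0.298` sum to 0.748, jointly
calibrated so that health-system costs are 42.8% of the grand total
(`0.748/1.748`); the published figure pins down only the sum, so the split
between the two levels is configuration.

**HPP costing** is the same engine run on the `hpp == TRUE` subset; there is
no separate code path.

## Disaggregation

Shares by platform and timing are taken over de-duplicated service-delivery
cost and sum to 1; objective shares sum to 1 only together with the
`unallocated` remainder, which carries pathology-type support interventions
(flagged explicitly, never inferred). Because markups are pro-rata, shares of
the grand total equal shares of service-delivery cost, so the choice of basis
is presentational. Combined-group shares pool summed costs across groups —
averaging per-group shares would weight the groups incorrectly.

## Sensitivity analysis

Uncertainty enters as multiplicative perturbations on six parameter families:
unit cost, baseline coverage, the two markups, population in need, and a
fertility proxy (populations in need of the maternal/newborn, child, and
reproductive-health packages, ids 1, 2, 5 — the family through which fertility
uncertainty propagates). One-way analysis re-runs the engine at the low and
high multiplier of one family, all else at point values; `tornado()` sorts
families by swing.

The PSA draws independent joint settings (no information on joint
distributions, so independence is assumed), re-evaluates the full engine per
draw, and summarises with empirical quantiles using linear interpolation
between order statistics (`stats::quantile` type 7) — stated so credible
intervals are comparable across implementations. Choices made where the
design was open:

* **Distribution default: uniform** over `(low, high)` — the
  least-information choice given only a plausible range. Triangular (mode at
  the point) and lognormal (median at the point, range read as the 2.5th and
  97.5th percentiles, support unbounded) are available per parameter.
* **Shipped default ranges** are documented stand-ins, user-overridable:
  unit cost ±50%, baseline coverage ±20%, markups ±25%, population in need
  ±20%, fertility proxy ±10%.
* **Grouping: one multiplier per family per intervention** per draw (not one
  per (intervention, group) cell), mirroring the one-way structure;
  `"per_cell"` and `"global"` are available. Note the consequence: with ~218
  interventions drawing independently, aggregate credible intervals are much
  narrower than those from one shared multiplier — reproducing published-width
  intervals (upper endpoint around twice the lower) requires
  `grouping = "global"`, i.e. treating unit-cost uncertainty as systematic
  rather than idiosyncratic. We keep the per-intervention default and expose
  the knob rather than silently widening intervals.
* **RNG contract:** one root seed; each parameter draws from its own
  deterministic substream (`seed + i·1000003 mod 2³¹−1`), so adding a
  parameter never perturbs another's draws, and a fixed seed gives
  bit-identical summaries. Generators save and restore the caller's
  `.Random.seed`.

## The synthetic generator and what a green test establishes

`generate_registry()` emulates the *structure* of the EUHC dataset: 218
interventions, 21 overlapping packages (primary membership uniform, extra
memberships Poisson with mean `overlap_rate = 0.15`, matching a cost
duplication factor of roughly 1.15 between total and de-duplicated
service-delivery cost), 115 HPP members, five platforms, three timing
classes, five objectives plus an unallocated pathology remainder, and the two
stylised groups (LIC 0.90 bn people / \$0.70 tn GNI; lower-MIC 2.7 bn /
\$5.9 tn). Where no published value exists, defaults were chosen once as
field-plausible and documented: unit costs log-uniform over \$0.5–500 per
beneficiary-year (the order-of-magnitude span implied by published package
costs), populations in need log-uniform over 0.1–30% of group population,
baseline coverage Beta(2, 6) (mean 0.25, consistent with baseline costs being
roughly a fifth to a third of total costs in the published aggregates),
traded fraction Beta(3, 7) (mean 0.30), source-setting GNI per capita
log-uniform \$500–15 000, price years 2000–2016. Urgent interventions are
costed per episode (rate 0.5–4/yr), others per patient-year.

`calibrated_fixture()` additionally matches the published *shares* of
incremental cost: platform 1.6 / 11.8 / 49.8 / 31.0 / 5.8% and timing 28.5 /
45.5 / 26.0% (groups combined, default policy). Calibration keeps the
categorical draw and then applies iterative proportional fitting (IPF) of
per-category unit-cost scale factors on the platform × timing
incremental-cost matrix until both marginals match (tolerance 1e−9, far
inside the ±1 percentage-point contract). We calibrate cost mass rather than
re-drawing category memberships because membership moves are discrete: with
heavy-tailed unit costs a single intervention can carry several percent of
total cost, so reassignment cannot reliably land within a percentage point,
and IPF converges for any seed. If a rare category (platform weight 1.6%) is
empty for an unlucky seed, one cheapest intervention is reassigned to it
before fitting.

What a green test does **not** establish: absolute dollar levels. Calibration
targets shares only; the fixture's totals are orders of magnitude away from
real EUHC costs, which depend on a proprietary unit-cost dataset that is out
of scope. Nor does the generator reproduce real intervention names,
correlations between cost and coverage, or country heterogeneity within a
group.

## Numerical and degenerate-input conventions

* Money is double-precision USD throughout; rounding to two significant
  figures happens only at render time (`render_2sf()`), in reports.
* Proportions are decimals in [0, 1] in all files and interfaces.
* Degenerate inputs: zero population in need or zero coverage cost zero;
  empty selections in `share_by()` and zero-cost denominators are usage
  errors; `population <= 0` or `gni <= 0` are validation errors; a
  per-episode cost without an episode rate is caught at validation, not at
  annualisation time.
* Validation returns diagnostics (one per violation, naming row and field)
  rather than raising, so a registry can be repaired in one pass; loaders
  raise on the collected diagnostics.

## Limitations

Beyond the synthetic-data caveats above: the model has no year-over-year
budget trajectory, no financing-source split, no economies of scale, no
country-specific registries, and no joint parameter priors. The bundled
deflator is a stand-in. Incremental costs assume the baseline is maintained
by whoever currently pays for it; the baseline estimate does not distinguish
public from private sources.
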