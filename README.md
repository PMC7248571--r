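# hbpcost

Counterfactual costing of essential health-benefits packages (HBPs) for
universal health coverage in stylised low-income (LIC) and lower-middle-income
(lower-MIC) country groups.

Health planners assembling an HBP — the list of interventions a UHC system
guarantees to finance — need an estimate of what delivering the whole package
would cost at a realistic coverage target, how that cost splits across
delivery platforms, timing of care, and health-system objectives, and how
uncertain the total is. `hbpcost` implements that costing engine for
registries structured like the 218-intervention essential-UHC (EUHC) model
package and its 115-intervention highest-priority (HPP) subset, with a seeded
synthetic-registry generator so the whole pipeline runs with no external data.

## Model

For intervention *i* in country group *g*, a raw study unit cost is
standardised in three steps:

1. **2016 USD**: `c = value × fx(currency, year) / index(year)` —
   exchange-rate conversion (not PPP) and inflation to the 2016 base.
2. **Setting transfer**: `c' = c × [τ + (1 − τ) · GNIpc_g / GNIpc_source]`,
   where `τ` is the traded-input fraction; traded inputs keep world market
   prices, non-traded inputs scale with per-capita GNI.
3. **Annualisation**: per-episode costs are multiplied by episodes per
   beneficiary-year; per-patient-year costs pass through.

Annual service-delivery (SD) costs at coverage `v` are
`u_ig = c'_ig × N_ig × v`, with `N_ig` the population in need. With baseline
coverage `b_ig` and target coverage `t` (default 0.80):

```
baseline_ig    = u(b_ig)
total_ig       = u(max(b_ig, t))     # above-target coverage is maintained
incremental_ig = total_ig − baseline_ig
```

Package totals sum every member intervention (overlapping memberships count
in each package, so the 21 package shares exceed 100%); the **de-duplicated**
total counts each intervention once. Facility and above-facility
health-system costs are markups on the de-duplicated SD total (defaults 0.45
and 0.298, calibrated so health-system costs are 42.8% of the grand total):

```
grand_total = dedup_SD × (1 + m_fac + m_above)
```

Affordability metrics divide by group population (per capita) or GNI (% of
GNI). Costs disaggregate by delivery platform, delivery timing, objective,
and package; one-way (tornado) and probabilistic sensitivity analysis
(default 10 000 Monte Carlo draws, independent parameters, empirical
2.5th/97.5th percentiles) quantify uncertainty.

## Worked example

```r
library(hbpcost)

reg <- calibrated_fixture(seed = 1)   # 218 interventions, 115 HPP, 21 packages
summ <- cost_summary(reg)
summ[, c("group", "grand_total", "total_per_capita", "incremental_pct_gni")]
#>       group grand_total total_per_capita incremental_pct_gni
#> 1       LIC    1.02e+12             1134               105.7
#> 2 lower-MIC    6.01e+12             2225                68.8
#> 3  combined    7.03e+12             1952                72.8

res <- cost_registry(reg)
round(100 * share_by(res, reg, "platform", cost = "incremental"), 1)
#>            population_based                   community
#>                         1.6                        11.8
#>               health_centre        first_level_hospital
#>                        49.8                        31.0
#> referral_specialty_hospital
#>                         5.8

run_psa(reg, config = psa_config(n_sims = 2000, seed = 1),
        metric = "incremental", scale = "pct_gni", groups = "LIC")
#> <psa_summary> incremental (pct_gni): point 105.7, 95% CrI [88.36, 123.7] (2000 draws)
```

`grand_total` is annual USD(2016): de-duplicated service delivery plus
health-system markups. The platform shares of incremental cost are the
calibration targets of the fixture (the published structure). The PSA line is
the incremental cost as a percentage of LIC GNI with its 95% credible
interval. **The fixture's dollar totals are synthetic**: calibration targets
cost *shares* only, never absolute dollars, which depend on a real unit-cost
dataset that is not shipped — hence per-capita figures far above published
EUHC estimates. Use the engine on a real registry for absolute levels.

## Registry files

CSV registries are a trio: the flat table (one row per intervention per
group) plus `<name>_groups.csv` (`id,population,gni_total`) and
`<name>_packages.csv` (`id,name`). JSON registries embed all three. Columns
of the flat table (proportions are decimals in [0,1], money is unrounded
USD):

```
id,name,packages,platform,timing,objective,hpp,pathology,group,
unit_cost_value,unit_cost_currency,unit_cost_price_year,
source_gni_per_capita,cost_basis,episodes_per_beneficiary_year,
traded_fraction,population_in_need,baseline_coverage
```

`packages` is a `|`-separated list of integer ids (1–21). The bundled
deflator/exchange-rate table is `inst/extdata/indices.csv`
(`year,index,currency,fx_rate`); override via `default_price_index(path)`.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hbpcost", package = "hbpcost"))')
Rscript $CLI synth --seed 1 --out data/                  # write a registry
Rscript $CLI validate --registry data/registry.csv
Rscript $CLI cost --registry data/registry.csv --out out/ [--package-set hpp]
Rscript $CLI disaggregate --registry data/registry.csv --by timing --cost incremental --out out/
Rscript $CLI oneway --registry data/registry.csv --out out/
Rscript $CLI psa --registry data/registry.csv --n-sims 10000 --seed 1 --out out/
```

Exit codes: 0 ok, 1 runtime error, 2 usage/validation error. All commands
accept `--config config.json` (keys such as `target_coverage`,
`facility_markup`, `above_facility_markup`, `default_traded_fraction`,
`n_sims`); flags win over config values. Every run writes a
`provenance.json` (input hashes, config, seed) sufficient to reproduce its
outputs. Reports round to two significant figures at render time only.

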