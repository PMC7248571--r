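# Standardisation of raw study unit costs to 2016 USD for a target stylised
# country group: currency conversion + inflation, traded/non-traded transfer,
# and annualisation of per-episode costs.

#' Construct a price-index series
#'
#' Bundles a deflator (base year 2016 == 1.0) with an exchange-rate table
#' mapping (currency, year) to USD. Conversion is exchange-rate based, not
#' PPP, so traded inputs keep world market prices.
#'
#' @param index data frame with columns `year`, `index` (index > 0, base year
#'   2016 present with index 1).
#' @param fx data frame with columns `currency`, `year`, `fx_rate` (units of
#'   USD per unit of currency in that year).
#' @return object of class `price_index_series`.
#' @export
price_index_series <- function(index, fx) {
  index <- as.data.frame(index, stringsAsFactors = FALSE)
  fx <- as.data.frame(fx, stringsAsFactors = FALSE)
  stopifnot(all(c("year", "index") %in% names(index)),
            all(c("currency", "year", "fx_rate") %in% names(fx)))
  if (any(index$index <= 0)) stop_validation("price index values must be > 0")
  if (!2016 %in% index$year) stop_validation("price index must include base year 2016")
  base <- index$index[index$year == 2016][1]
  if (abs(base - 1) > 1e-12) stop_validation("price index base year 2016 must equal 1.0")
  structure(list(index = index, fx = fx), class = "price_index_series")
}

#' Default bundled price-index and exchange-rate series
#'
#' A documented stand-in: a US-GDP-deflator-style series for 1990-2016 at a
#' constant 2% annual rate, USD only. Users with a preferred deflator or
#' multi-currency data should supply their own `indices.csv` (columns `year`,
#' `index`, `currency`, `fx_rate`) via `path`.
#'
#' @param path optional CSV overriding the bundled series.
#' @return a [price_index_series()].
#' @export
default_price_index <- function(path = NULL) {
  path <- path %||% system.file("extdata", "indices.csv", package = "hbpcost")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  price_index_series(index = unique(tab[c("year", "index")]),
                     fx = tab[c("currency", "year", "fx_rate")])
}

index_at <- function(series, year) {
  i <- match(year, series$index$year)
  if (anyNA(i)) {
    stop_usage("price index has no entry for year(s): ",
               paste(unique(year[is.na(i)]), collapse = ", "))
  }
  series$index$index[i]
}

fx_at <- function(series, currency, year) {
  key <- paste(series$fx$currency, series$fx$year)
  i <- match(paste(currency, year), key)
  if (anyNA(i)) {
    bad <- unique(paste0("(", currency, ", ", year, ")")[is.na(i)])
    stop_usage("no exchange rate for ", paste(bad, collapse = ", "))
  }
  series$fx$fx_rate[i]
}

#' Convert and inflate a cost to 2016 US dollars
#'
#' `value * fx_rate(currency, price_year) * index(2016) / index(price_year)`,
#' i.e. exchange-rate conversion in the price year followed by inflation to
#' the 2016 base.
#'
#' @param value amount in `currency` at `price_year` prices.
#' @param currency ISO currency code present in the series.
#' @param price_year calendar year present in the series.
#' @param series a [price_index_series()].
#' @return USD(2016) amount. Vectorised over all cost arguments.
#' @export
to_usd_2016 <- function(value, currency, price_year, series = default_price_index()) {
  value * fx_at(series, currency, price_year) / index_at(series, price_year)
}

#' Transfer a unit cost between settings via GNI per capita
#'
#' Splits the cost into a traded component (world market prices, transferred
#' unchanged) and a non-traded component (local salaries and services, scaled
#' by the ratio of target to source GNI per capita):
#' `cost * (traded + (1 - traded) * target_gni_pc / source_gni_pc)`.
#'
#' @param cost_usd2016 standardised cost, USD(2016).
#' @param traded_fraction proportion of the unit cost attributable to traded
#'   inputs, in \[0, 1\].
#' @param source_gni_pc GNI per capita of the costing study's setting (> 0).
#' @param target_gni_pc GNI per capita of the target group (> 0).
#' @return transferred USD(2016) cost. Vectorised.
#' @export
transfer_unit_cost <- function(cost_usd2016, traded_fraction, source_gni_pc,
                               target_gni_pc) {
  if (any(traded_fraction < 0 | traded_fraction > 1)) {
    stop_validation("traded_fraction must be in [0, 1]")
  }
  if (any(source_gni_pc <= 0) || any(target_gni_pc <= 0)) {
    stop_validation("GNI per capita must be > 0")
  }
  cost_usd2016 * (traded_fraction + (1 - traded_fraction) * target_gni_pc / source_gni_pc)
}

#' Annualise a unit cost to USD per beneficiary-year
#'
#' Per-patient-year costs pass through; per-episode costs are multiplied by
#' the expected episodes per beneficiary per year.
#'
#' @param value standardised unit cost.
#' @param cost_basis `"per_patient_year"` or `"per_episode"`.
#' @param episodes_per_beneficiary_year required (> 0) iff `per_episode`.
#' @return USD per beneficiary-year. Vectorised.
#' @export
annualize <- function(value, cost_basis, episodes_per_beneficiary_year = NA) {
  if (!all(cost_basis %in% hbp_cost_bases)) stop_validation("invalid cost_basis")
  ep <- cost_basis == "per_episode"
  if (any(ep & (is.na(episodes_per_beneficiary_year) |
                episodes_per_beneficiary_year <= 0))) {
    stop_validation("per_episode costs require episodes_per_beneficiary_year > 0")
  }
  ifelse(ep, value * episodes_per_beneficiary_year, value)
}

#' Standardise every unit cost in a registry
#'
#' Applies [to_usd_2016()], [transfer_unit_cost()] (target GNI per capita
#' taken from each row's country group), and [annualize()], adding the column
#' `unit_cost_py` (USD(2016) per beneficiary-year in the target setting) to
#' the intervention table.
#'
#' @param registry an `hbp_registry`.
#' @param series a [price_index_series()].
#' @return the registry with `interventions$unit_cost_py` populated.
#' @export
standardize_registry <- function(registry, series = default_price_index()) {
  iv <- registry$interventions
  target_gni_pc <- registry$groups$gni_per_capita[
    match(iv$group, registry$groups$id)]
  usd <- to_usd_2016(iv$unit_cost_value, iv$unit_cost_currency,
                     iv$unit_cost_price_year, series)
  moved <- transfer_unit_cost(usd, iv$traded_fraction,
                              iv$source_gni_per_capita, target_gni_pc)
  iv$unit_cost_py <- annualize(moved, iv$cost_basis,
                               iv$episodes_per_beneficiary_year)
  registry$interventions <- iv
  registry
}
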