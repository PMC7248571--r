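# Core counterfactual costing: baseline, incremental, and total annual
# service-delivery costs per intervention and group; de-duplicated and
# per-package aggregation; health-system markups; affordability metrics.

#' Coverage policy for counterfactual costing
#'
#' The counterfactual asks what delivering every intervention at a target
#' coverage (default 80%, a realistic and consistent target for the SDG era)
#' would cost, relative to current baseline coverage. Interventions already
#' above target are maintained, not cut, when `clamp_negative_increments` is
#' `TRUE` (the default); turning clamping off makes the total the cost at
#' exactly the target, so increments can be negative.
#'
#' @param target_coverage proportion of the population in need reached, in
#'   (0, 1\].
#' @param clamp_negative_increments maintain above-target coverage (default
#'   `TRUE`).
#' @return object of class `coverage_policy`.
#' @export
coverage_policy <- function(target_coverage = 0.80,
                            clamp_negative_increments = TRUE) {
  if (!is.numeric(target_coverage) || target_coverage <= 0 || target_coverage > 1) {
    stop_validation("target_coverage must be in (0, 1]")
  }
  structure(list(target_coverage = target_coverage,
                 clamp_negative_increments = isTRUE(clamp_negative_increments)),
            class = "coverage_policy")
}

#' Health-system markup configuration
#'
#' Facility-level costs (rent, utilities, maintenance) and above-facility
#' costs (supply chain, financing, information systems, administration) are
#' modelled as proportional markups on de-duplicated service-delivery cost;
#' in-service training is assumed inside the markups. The defaults (facility
#' 0.45, above-facility 0.298, sum 0.748) are jointly calibrated so the
#' health-system share of the grand total is 42.8% — the split between the
#' two levels is configuration, the calibrated sum is what the share pins
#' down.
#'
#' @param facility proportion of service-delivery cost, >= 0.
#' @param above_facility proportion of service-delivery cost, >= 0.
#' @return object of class `markup_config`.
#' @export
markup_config <- function(facility = 0.45, above_facility = 0.298) {
  if (facility < 0 || above_facility < 0) stop_validation("markups must be >= 0")
  structure(list(facility = facility, above_facility = above_facility),
            class = "markup_config")
}

#' Annual service-delivery cost at a given coverage
#'
#' `unit_cost_py * population_in_need * coverage`.
#'
#' @param unit_cost_py standardised unit cost, USD(2016)/beneficiary-year.
#' @param population_in_need persons (or episode-eligible persons) per year.
#' @param coverage proportion of the population in need reached, in \[0, 1\].
#' @return USD per year. Vectorised.
#' @export
annual_sd_cost <- function(unit_cost_py, population_in_need, coverage) {
  if (any(coverage < 0 | coverage > 1)) stop_validation("coverage must be in [0, 1]")
  unit_cost_py * population_in_need * coverage
}

#' Baseline, incremental, and total cost of one intervention
#'
#' Baseline is the cost at current coverage; total is the cost at
#' `max(baseline, target)` under clamping (at the target otherwise);
#' incremental is their difference, so `total == baseline + incremental` by
#' construction.
#'
#' @inheritParams annual_sd_cost
#' @param baseline_coverage current coverage, in \[0, 1\].
#' @param policy a [coverage_policy()].
#' @return data frame with columns `baseline_sd`, `incremental_sd`,
#'   `total_sd` (USD/yr). Vectorised.
#' @export
cost_intervention <- function(unit_cost_py, population_in_need,
                              baseline_coverage, policy = coverage_policy()) {
  baseline <- annual_sd_cost(unit_cost_py, population_in_need, baseline_coverage)
  eff_target <- if (policy$clamp_negative_increments) {
    pmax(baseline_coverage, policy$target_coverage)
  } else {
    rep(policy$target_coverage, length.out = length(baseline_coverage))
  }
  total <- annual_sd_cost(unit_cost_py, population_in_need, eff_target)
  data.frame(baseline_sd = baseline, incremental_sd = total - baseline,
             total_sd = total)
}

#' Cost every intervention in a registry
#'
#' Standardises unit costs (unless `registry$interventions$unit_cost_py` is
#' already present) and computes the per-(intervention, group) service-delivery
#' cost triple.
#'
#' @param registry an `hbp_registry`.
#' @param policy a [coverage_policy()].
#' @param series a [price_index_series()] used if standardisation is needed.
#' @param hpp_only restrict to the highest-priority subset (`hpp == TRUE`).
#'   The HPP is costed by the same engine on the subset; there is no separate
#'   code path.
#' @return data frame of class `hbp_costs`: `id`, `group`, `package` list
#'   column omitted (join back to the registry for classification), plus
#'   `baseline_sd`, `incremental_sd`, `total_sd`.
#' @export
cost_registry <- function(registry, policy = coverage_policy(),
                          series = default_price_index(), hpp_only = FALSE) {
  if (is.null(registry$interventions$unit_cost_py)) {
    registry <- standardize_registry(registry, series)
  }
  iv <- registry$interventions
  if (hpp_only) iv <- iv[iv$hpp, , drop = FALSE]
  res <- cost_intervention(iv$unit_cost_py, iv$population_in_need,
                           iv$baseline_coverage, policy)
  out <- cbind(data.frame(id = iv$id, group = iv$group,
                          stringsAsFactors = FALSE), res)
  class(out) <- c("hbp_costs", class(out))
  out
}

select_results <- function(results, ids = NULL, groups = NULL) {
  keep <- rep(TRUE, nrow(results))
  if (!is.null(ids)) {
    unknown <- setdiff(ids, results$id)
    if (length(unknown) > 0) {
      stop_usage("unknown intervention id(s): ", paste(unknown, collapse = ", "))
    }
    keep <- keep & results$id %in% ids
  }
  if (!is.null(groups)) keep <- keep & results$group %in% groups
  results[keep, , drop = FALSE]
}

#' De-duplicated cost total over a selection
#'
#' Sums costs over unique interventions: membership in several packages never
#' multiplies an intervention's cost.
#'
#' @param results an `hbp_costs` table from [cost_registry()].
#' @param ids optional intervention ids to select (default: all).
#' @param groups optional group ids to pool (default: all).
#' @param field one of `"baseline_sd"`, `"incremental_sd"`, `"total_sd"`.
#' @return USD per year.
#' @export
dedup_total <- function(results, ids = NULL, groups = NULL, field = "total_sd") {
  field <- match.arg(field, c("baseline_sd", "incremental_sd", "total_sd"))
  sel <- select_results(results, ids, groups)
  # results carry one row per (id, group); summing rows IS the de-duplicated
  # total. Duplication only arises when summing per-package totals.
  sum(sel[[field]])
}

#' Cost total of one package
#'
#' Sums over all interventions belonging to the package. Interventions shared
#' with other packages are intentionally counted in each: the package share
#' of the de-duplicated total reads as the cost that would remain if all
#' other packages were removed, and the 21 shares sum to more than 100%.
#'
#' @param results an `hbp_costs` table.
#' @param registry the registry the results came from.
#' @param package_id integer package id.
#' @inheritParams dedup_total
#' @return USD per year.
#' @export
package_total <- function(results, registry, package_id, groups = NULL,
                          field = "total_sd") {
  if (!package_id %in% registry$packages$id) {
    stop_usage("unknown package id: ", package_id)
  }
  membership <- parse_package_ids(registry$interventions$packages)
  member_rows <- vapply(membership, function(p) package_id %in% p, logical(1))
  member_ids <- unique(registry$interventions$id[member_rows])
  # Members outside the costed selection (e.g. non-HPP rows in an HPP run)
  # contribute nothing.
  member_ids <- intersect(member_ids, results$id)
  if (length(member_ids) == 0) return(0)
  dedup_total(results, ids = member_ids, groups = groups, field = field)
}

#' Apply health-system markups to a de-duplicated total
#'
#' @param dedup_sd de-duplicated service-delivery cost, USD/yr (>= 0).
#' @param markups a [markup_config()].
#' @return list with `health_system` (USD/yr) and `grand_total`
#'   (`dedup_sd + health_system`).
#' @export
apply_markups <- function(dedup_sd, markups = markup_config()) {
  if (any(dedup_sd < 0)) stop_validation("dedup_sd must be >= 0")
  hs <- dedup_sd * (markups$facility + markups$above_facility)
  list(health_system = hs, grand_total = dedup_sd + hs)
}

#' Cost per capita
#'
#' @param cost USD per year.
#' @param group a one-row group data frame (or any list with `population`).
#' @return USD per person per year.
#' @export
per_capita <- function(cost, group) {
  if (any(group$population <= 0)) stop_validation("population must be > 0")
  cost / group$population
}

#' Cost as a share of GNI
#'
#' @param cost USD per year.
#' @param group a one-row group data frame (or any list with `gni_total`).
#' @return proportion of annual GNI (multiply by 100 to print a percentage).
#' @export
share_of_gni <- function(cost, group) {
  if (any(group$gni_total <= 0)) stop_validation("gni_total must be > 0")
  cost / group$gni_total
}

#' Aggregate cost summary for a registry
#'
#' Reproduces the structure of a package-totals report: per group (and for
#' all groups combined) the duplicated service-delivery total, the
#' de-duplicated baseline / incremental / total, health-system cost, grand
#' totals (baseline-, incremental-, and total-basis), and per-capita and
#' %-GNI affordability metrics. Markups apply to de-duplicated totals only.
#'
#' @param registry an `hbp_registry`.
#' @param results optional precomputed `hbp_costs` (recomputed otherwise).
#' @param policy a [coverage_policy()].
#' @param markups a [markup_config()].
#' @param hpp_only cost only the highest-priority subset.
#' @param series a [price_index_series()].
#' @return data frame, one row per group plus a `combined` row.
#' @export
cost_summary <- function(registry, results = NULL, policy = coverage_policy(),
                         markups = markup_config(), hpp_only = FALSE,
                         series = default_price_index()) {
  if (is.null(results)) {
    results <- cost_registry(registry, policy, series, hpp_only = hpp_only)
  } else if (hpp_only) {
    hpp_ids <- unique(registry$interventions$id[registry$interventions$hpp])
    results <- select_results(results, ids = hpp_ids)
  }
  membership <- parse_package_ids(registry$interventions$packages)
  n_memberships <- vapply(membership, length, integer(1))
  mult <- n_memberships[match(results$id, registry$interventions$id)]

  one_group <- function(gid) {
    sel <- if (identical(gid, "combined")) results else
      results[results$group == gid, , drop = FALSE]
    m <- if (identical(gid, "combined")) mult else mult[results$group == gid]
    pop <- if (identical(gid, "combined")) sum(registry$groups$population) else
      registry$groups$population[registry$groups$id == gid]
    gni <- if (identical(gid, "combined")) sum(registry$groups$gni_total) else
      registry$groups$gni_total[registry$groups$id == gid]
    dedup_b <- sum(sel$baseline_sd)
    dedup_i <- sum(sel$incremental_sd)
    dedup_t <- sum(sel$total_sd)
    mk <- apply_markups(dedup_t, markups)
    data.frame(
      group = gid,
      total_sd = sum(sel$total_sd * m),           # with duplication
      dedup_baseline_sd = dedup_b,
      dedup_incremental_sd = dedup_i,
      dedup_total_sd = dedup_t,
      health_system = mk$health_system,
      grand_total = mk$grand_total,
      grand_baseline = dedup_b * (1 + markups$facility + markups$above_facility),
      grand_incremental = dedup_i * (1 + markups$facility + markups$above_facility),
      total_per_capita = mk$grand_total / pop,
      incremental_per_capita = dedup_i *
        (1 + markups$facility + markups$above_facility) / pop,
      total_pct_gni = 100 * mk$grand_total / gni,
      incremental_pct_gni = 100 * dedup_i *
        (1 + markups$facility + markups$above_facility) / gni,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(c(registry$groups$id, "combined"), one_group))
}
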