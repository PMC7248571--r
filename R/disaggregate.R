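# Decomposition of costs by delivery platform, delivery timing, health-system
# objective, and package. Shares are taken over de-duplicated service-delivery
# costs; health-system markups cancel in any pro-rata allocation, so shares of
# the grand total are identical. Combined-group shares pool summed costs
# across groups (never averaged shares).

dimension_levels <- function(dimension) {
  switch(dimension,
         platform = hbp_platforms,
         timing = hbp_timings,
         objective = hbp_objectives,
         stop_usage("unknown dimension: ", dimension))
}

#' Cost shares by intervention characteristic
#'
#' For `platform` and `timing` the shares are over the de-duplicated cost of
#' the selection and sum to 1. For `objective` the five substantive objective
#' shares plus the `unallocated` remainder (pathology-type support
#' interventions) sum to 1. For `package` each share is that package's total
#' over the de-duplicated total; overlapping memberships make the 21 shares
#' sum to more than 100%.
#'
#' @param results an `hbp_costs` table from [cost_registry()].
#' @param registry the registry the results came from.
#' @param dimension one of `"platform"`, `"timing"`, `"objective"`,
#'   `"package"`.
#' @param cost `"incremental"` or `"total"` (service-delivery basis).
#' @param groups optional group ids to pool (default: all groups combined).
#' @return named numeric vector of proportions over the dimension levels.
#' @export
share_by <- function(results, registry,
                     dimension = c("platform", "timing", "objective", "package"),
                     cost = c("incremental", "total"), groups = NULL) {
  dimension <- match.arg(dimension)
  cost <- match.arg(cost)
  field <- paste0(cost, "_sd")
  sel <- select_results(results, groups = groups)
  if (nrow(sel) == 0) stop_usage("empty selection")
  denom <- sum(sel[[field]])
  if (denom <= 0) stop_usage("selection has zero ", cost, " cost")

  if (dimension == "package") {
    shares <- vapply(registry$packages$id, function(p) {
      package_total(results, registry, p, groups = groups, field = field) / denom
    }, numeric(1))
    names(shares) <- as.character(registry$packages$id)
    return(shares)
  }

  cat_of <- registry$interventions[[dimension]][
    match(sel$id, registry$interventions$id)]
  levels <- dimension_levels(dimension)
  sums <- vapply(levels, function(l) sum(sel[[field]][cat_of == l]), numeric(1))
  shares <- sums / denom
  names(shares) <- levels
  shares
}

#' Cost distribution by health-system objective
#'
#' One row per objective (including the `unallocated` pathology remainder)
#' and a reconciling `total` row: intervention counts, grand-total cost
#' (markups allocated pro rata), percent of group GNI, and share of overall
#' cost. The substantive-objective rows sum to slightly less than the total
#' row exactly when unallocated pathology cost is present.
#'
#' @param results an `hbp_costs` table.
#' @param registry the registry the results came from.
#' @param group a group id (or `NULL` for all groups combined).
#' @param cost `"total"` (default) or `"incremental"`.
#' @param markups a [markup_config()].
#' @return data frame with columns `objective`, `n_interventions`, `cost`,
#'   `pct_gni`, `share`.
#' @export
objective_table <- function(results, registry, group = NULL, cost = "total",
                            markups = markup_config()) {
  field <- paste0(match.arg(cost, c("total", "incremental")), "_sd")
  sel <- select_results(results, groups = group)
  gni <- if (is.null(group)) sum(registry$groups$gni_total) else
    registry$groups$gni_total[registry$groups$id == group]
  factor <- 1 + markups$facility + markups$above_facility
  obj_of <- registry$interventions$objective[
    match(sel$id, registry$interventions$id)]
  total_cost <- sum(sel[[field]]) * factor
  rows <- lapply(hbp_objectives, function(o) {
    in_o <- obj_of == o
    cost_o <- sum(sel[[field]][in_o]) * factor
    data.frame(objective = o,
               n_interventions = length(unique(sel$id[in_o])),
               cost = cost_o,
               pct_gni = 100 * cost_o / gni,
               share = if (total_cost > 0) cost_o / total_cost else 0,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rbind(tab,
        data.frame(objective = "total",
                   n_interventions = length(unique(sel$id)),
                   cost = total_cost, pct_gni = 100 * total_cost / gni,
                   share = if (total_cost > 0) 1 else 0,
                   stringsAsFactors = FALSE))
}
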