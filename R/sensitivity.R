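# One-way (tornado) and probabilistic (Monte Carlo) sensitivity analysis.
#
# Uncertainty enters as multiplicative perturbations on parameter families:
# unit costs, baseline coverage, the two health-system markups, populations
# in need, and a fertility proxy (populations in need of the maternal/child/
# reproductive-health packages, ids 1, 2, 5). Every draw re-evaluates the
# full engine; draws for different parameters come from separate documented
# RNG substreams of one root seed, so adding a parameter never perturbs
# another parameter's draws.

hbp_param_families <- c("unit_cost", "baseline_coverage", "facility_markup",
                        "above_facility_markup", "population_in_need",
                        "fertility_proxy")
fertility_packages <- c(1L, 2L, 5L)

#' An uncertain model parameter
#'
#' A multiplicative perturbation on one parameter family, with a plausible
#' range `[low, high]` around the `point` multiplier (1 leaves the input at
#' its registry value).
#'
#' @param target parameter family: one of `"unit_cost"`,
#'   `"baseline_coverage"`, `"facility_markup"`, `"above_facility_markup"`,
#'   `"population_in_need"`, `"fertility_proxy"`.
#' @param low,high range endpoints (multipliers, `0 <= low <= point <= high`).
#' @param point point-estimate multiplier (default 1).
#' @param family distribution over the range: `"uniform"` (default,
#'   least-information given a stated range), `"triangular"` (mode at
#'   `point`), or `"lognormal"` (median `point`, `low`/`high` as the 2.5th and
#'   97.5th percentiles; unbounded support).
#' @param grouping `"per_intervention"` (default: one multiplier per
#'   intervention per draw, independent across interventions),
#'   `"global"` (one shared multiplier), or `"per_cell"` (one per
#'   (intervention, group) record). Markup families are always global.
#' @return object of class `uncertain_param`.
#' @export
uncertain_param <- function(target, low, high, point = 1,
                            family = c("uniform", "triangular", "lognormal"),
                            grouping = c("per_intervention", "global", "per_cell")) {
  target <- match.arg(target, hbp_param_families)
  family <- match.arg(family)
  grouping <- match.arg(grouping)
  if (grepl("markup", target)) grouping <- "global"
  if (!(low <= point && point <= high)) stop_validation("need low <= point <= high")
  if (low < 0) stop_validation("low must be >= 0 for nonnegative parameters")
  if (family == "lognormal" && low <= 0) {
    stop_validation("lognormal ranges require low > 0")
  }
  structure(list(target = target, low = low, high = high, point = point,
                 family = family, grouping = grouping),
            class = "uncertain_param")
}

#' Shipped default plausible ranges
#'
#' Documented stand-ins, user-overridable: unit cost +/-50%, baseline coverage
#' +/-20%, both markups +/-25%, population in need +/-20%, fertility proxy
#' +/-10%; all uniform.
#'
#' @param grouping passed to [uncertain_param()] for the non-markup families.
#' @return list of [uncertain_param()] objects.
#' @export
default_uncertain_params <- function(grouping = "per_intervention") {
  list(uncertain_param("unit_cost", 0.5, 1.5, grouping = grouping),
       uncertain_param("baseline_coverage", 0.8, 1.2, grouping = grouping),
       uncertain_param("facility_markup", 0.75, 1.25),
       uncertain_param("above_facility_markup", 0.75, 1.25),
       uncertain_param("population_in_need", 0.8, 1.2, grouping = grouping),
       uncertain_param("fertility_proxy", 0.9, 1.1, grouping = grouping))
}

#' Probabilistic sensitivity analysis settings
#'
#' @param n_sims Monte Carlo draws (default 10000).
#' @param seed root RNG seed.
#' @param percentiles credible-interval endpoints in percent (default 2.5 and
#'   97.5, i.e. a 95% credible interval).
#' @return object of class `psa_config`.
#' @export
psa_config <- function(n_sims = 10000, seed = 1L, percentiles = c(2.5, 97.5)) {
  if (n_sims < 1) stop_validation("n_sims must be >= 1")
  stopifnot(length(percentiles) == 2, all(percentiles >= 0 & percentiles <= 100))
  structure(list(n_sims = as.integer(n_sims), seed = as.integer(seed),
                 percentiles = as.numeric(percentiles)), class = "psa_config")
}

draw_multipliers <- function(param, n_sims, n_units, seed) {
  n <- n_sims * n_units
  draws <- with_seed(seed, {
    switch(param$family,
      uniform = stats::runif(n, param$low, param$high),
      triangular = {
        u <- stats::runif(n)
        a <- param$low; b <- param$high; c <- param$point
        if (b == a) rep(a, n) else {
          fc <- (c - a) / (b - a)
          ifelse(u < fc, a + sqrt(u * (b - a) * (c - a)),
                 b - sqrt((1 - u) * (b - a) * (b - c)))
        }
      },
      lognormal = {
        sdlog <- (log(param$high) - log(param$low)) / (2 * stats::qnorm(0.975))
        stats::rlnorm(n, meanlog = log(param$point), sdlog = sdlog)
      })
  })
  matrix(draws, nrow = n_sims, ncol = n_units)
}

# Internal evaluation context: standardised rows + index maps, built once.
psa_context <- function(registry, series = default_price_index(),
                        hpp_only = FALSE, groups = NULL) {
  if (is.null(registry$interventions$unit_cost_py)) {
    registry <- standardize_registry(registry, series)
  }
  iv <- registry$interventions
  keep <- rep(TRUE, nrow(iv))
  if (hpp_only) keep <- keep & iv$hpp
  if (!is.null(groups)) keep <- keep & iv$group %in% groups
  iv <- iv[keep, , drop = FALSE]
  if (nrow(iv) == 0) stop_usage("empty selection")
  grp <- registry$groups
  if (!is.null(groups)) grp <- grp[grp$id %in% groups, , drop = FALSE]
  fert <- vapply(parse_package_ids(iv$packages),
                 function(p) any(p %in% fertility_packages), logical(1))
  list(unit = iv$unit_cost_py, pop = iv$population_in_need,
       cov = iv$baseline_coverage, fert_rows = fert,
       intervention_index = match(iv$id, unique(iv$id)),
       n_interventions = length(unique(iv$id)),
       population = sum(grp$population), gni = sum(grp$gni_total))
}

# Evaluate the aggregate metric for one joint multiplier setting.
# mult: named list of row-level multiplier vectors and scalar markup
# multipliers. Returns a single number.
evaluate_setting <- function(ctx, policy, markups, metric, scale, mult) {
  unit <- ctx$unit * mult$unit_cost
  pop <- ctx$pop * mult$population_in_need *
    ifelse(ctx$fert_rows, mult$fertility_proxy, 1)
  cov <- pmin(pmax(ctx$cov * mult$baseline_coverage, 0), 1)
  baseline <- unit * pop * cov
  eff <- if (policy$clamp_negative_increments) pmax(cov, policy$target_coverage)
         else policy$target_coverage
  total <- unit * pop * eff
  dedup <- switch(metric, baseline = sum(baseline), total = sum(total),
                  incremental = sum(total - baseline))
  markup_rate <- markups$facility * mult$facility_markup +
    markups$above_facility * mult$above_facility_markup
  grand <- dedup * (1 + markup_rate)
  switch(scale, absolute = grand, per_capita = grand / ctx$population,
         pct_gni = 100 * grand / ctx$gni)
}

unit_multipliers <- function(ctx) {
  list(unit_cost = 1, baseline_coverage = 1, population_in_need = 1,
       fertility_proxy = 1, facility_markup = 1, above_facility_markup = 1)
}

#' One-way sensitivity of an aggregate metric
#'
#' Re-runs the full engine with one parameter family set to its low and high
#' multiplier (globally, all else at point values) and reports the swing.
#'
#' @param registry an `hbp_registry`.
#' @param family one of the parameter families (see [uncertain_param()]).
#' @param low_mult,high_mult multipliers (> 0; perturbed coverage is clipped
#'   to \[0, 1\]).
#' @param policy a [coverage_policy()].
#' @param markups a [markup_config()].
#' @param metric `"incremental"` (default), `"total"`, or `"baseline"` grand
#'   cost (de-duplicated, markups applied).
#' @param scale `"absolute"` (default), `"per_capita"`, or `"pct_gni"`.
#' @param groups optional group pooling; `hpp_only` restricts to the HPP.
#' @param hpp_only restrict to the highest-priority subset.
#' @param series a [price_index_series()].
#' @return list with `metric_low`, `metric_high`, `swing`.
#' @export
one_way <- function(registry, family, low_mult, high_mult,
                    policy = coverage_policy(), markups = markup_config(),
                    metric = c("incremental", "total", "baseline"),
                    scale = c("absolute", "per_capita", "pct_gni"),
                    groups = NULL, hpp_only = FALSE,
                    series = default_price_index()) {
  family <- match.arg(family, hbp_param_families)
  metric <- match.arg(metric)
  scale <- match.arg(scale)
  if (low_mult <= 0 || high_mult <= 0) stop_validation("multipliers must be > 0")
  ctx <- psa_context(registry, series, hpp_only, groups)
  at <- function(m) {
    mult <- unit_multipliers(ctx)
    mult[[family]] <- m
    evaluate_setting(ctx, policy, markups, metric, scale, mult)
  }
  lo <- at(low_mult); hi <- at(high_mult)
  list(metric_low = lo, metric_high = hi, swing = abs(hi - lo))
}

#' Tornado table over all parameter families
#'
#' @inheritParams one_way
#' @param ranges named list `family -> c(low, high)` multipliers; defaults to
#'   the shipped plausible ranges.
#' @return data frame (`parameter`, `low`, `high`, `swing`) sorted by
#'   decreasing swing.
#' @export
tornado <- function(registry, policy = coverage_policy(),
                    markups = markup_config(),
                    ranges = NULL, metric = "incremental", scale = "absolute",
                    groups = NULL, hpp_only = FALSE,
                    series = default_price_index()) {
  if (is.null(ranges)) {
    defaults <- default_uncertain_params()
    ranges <- stats::setNames(lapply(defaults, function(p) c(p$low, p$high)),
                              vapply(defaults, `[[`, "", "target"))
  }
  rows <- lapply(names(ranges), function(f) {
    r <- one_way(registry, f, ranges[[f]][1], ranges[[f]][2], policy, markups,
                 metric, scale, groups, hpp_only, series)
    data.frame(parameter = f, low = r$metric_low, high = r$metric_high,
               swing = r$swing, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$swing), , drop = FALSE]
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_sims` independent joint parameter settings (parameters are
#' independently distributed; each parameter has its own RNG substream of the
#' root seed), re-evaluates the full engine for each, and summarises the
#' metric with empirical percentiles (linear interpolation between order
#' statistics, `stats::quantile` type 7). A fixed seed yields bit-identical
#' summaries.
#'
#' @inheritParams one_way
#' @param params list of [uncertain_param()] (default: shipped ranges).
#' @param config a [psa_config()].
#' @param keep_draws retain the metric draws (and per-parameter multiplier
#'   draws) in the result.
#' @return object of class `psa_summary`: `point`, `lo`, `hi`, `n_sims`,
#'   `percentiles`, plus `draws` / `param_draws` when `keep_draws`.
#' @export
run_psa <- function(registry, params = default_uncertain_params(),
                    config = psa_config(), policy = coverage_policy(),
                    markups = markup_config(),
                    metric = c("incremental", "total", "baseline"),
                    scale = c("absolute", "per_capita", "pct_gni"),
                    groups = NULL, hpp_only = FALSE, keep_draws = FALSE,
                    series = default_price_index()) {
  metric <- match.arg(metric)
  scale <- match.arg(scale)
  ctx <- psa_context(registry, series, hpp_only, groups)
  n_rows <- length(ctx$unit)

  # One multiplier matrix (n_sims x units) per parameter, expanded to rows.
  param_draws <- vector("list", length(params))
  row_draws <- vector("list", length(params))
  for (i in seq_along(params)) {
    p <- params[[i]]
    n_units <- switch(p$grouping, global = 1L,
                      per_intervention = ctx$n_interventions,
                      per_cell = n_rows)
    d <- draw_multipliers(p, config$n_sims, n_units, stream_seed(config$seed, i))
    param_draws[[i]] <- d
    row_draws[[i]] <- switch(p$grouping,
      global = d[, rep(1L, n_rows), drop = FALSE],
      per_intervention = d[, ctx$intervention_index, drop = FALSE],
      per_cell = d)
    if (grepl("markup", p$target)) row_draws[[i]] <- d  # scalar per sim
  }
  targets <- vapply(params, `[[`, "", "target")

  draws <- numeric(config$n_sims)
  for (s in seq_len(config$n_sims)) {
    mult <- unit_multipliers(ctx)
    for (i in seq_along(params)) {
      m <- row_draws[[i]][s, ]
      mult[[targets[i]]] <- mult[[targets[i]]] * m
    }
    draws[s] <- evaluate_setting(ctx, policy, markups, metric, scale, mult)
  }

  point_mult <- unit_multipliers(ctx)
  for (i in seq_along(params)) {
    point_mult[[targets[i]]] <- point_mult[[targets[i]]] * params[[i]]$point
  }
  point <- evaluate_setting(ctx, policy, markups, metric, scale, point_mult)
  ci <- unname(stats::quantile(draws, probs = config$percentiles / 100, type = 7))

  out <- list(point = point, lo = ci[1], hi = ci[2], n_sims = config$n_sims,
              percentiles = config$percentiles, metric = metric, scale = scale)
  if (keep_draws) {
    out$draws <- draws
    out$param_draws <- stats::setNames(param_draws, targets)
  }
  structure(out, class = "psa_summary")
}

#' @export
print.psa_summary <- function(x, ...) {
  cat(sprintf("<psa_summary> %s (%s): point %.4g, %g%% CrI [%.4g, %.4g] (%d draws)\n",
              x$metric, x$scale, x$point,
              diff(x$percentiles), x$lo, x$hi, x$n_sims))
  invisible(x)
}
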