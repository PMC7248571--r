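test_that("annual_sd_cost and cost_intervention follow the coverage-gap rule", {
  expect_equal(annual_sd_cost(2, 1e6, 0.3), 6e5)
  expect_equal(annual_sd_cost(2, 1e6, 0), 0)
  expect_equal(annual_sd_cost(2, 0, 0.8), 0)
  expect_error(annual_sd_cost(2, 1e6, 1.2), class = "hbp_validation_error")

  r <- cost_intervention(2, 1e6, 0.3)
  expect_equal(r$baseline_sd, 6e5)
  expect_equal(r$incremental_sd, 1e6)
  expect_equal(r$total_sd, 1.6e6)

  # No gap at target.
  expect_equal(cost_intervention(2, 1e6, 0.8)$incremental_sd, 0)

  # Above target: clamped (maintained, not cut) by default ...
  above <- cost_intervention(2, 1e6, 0.9)
  expect_equal(above$incremental_sd, 0)
  expect_equal(above$total_sd, above$baseline_sd)
  # ... negative increment when clamping is off.
  nc <- cost_intervention(2, 1e6, 0.9, coverage_policy(0.8, FALSE))
  expect_equal(nc$incremental_sd, -2e5)
  expect_equal(nc$total_sd, 1.6e6)

  expect_error(coverage_policy(0), class = "hbp_validation_error")
  expect_error(coverage_policy(1.1), class = "hbp_validation_error")
})

test_that("total_sd == baseline_sd + incremental_sd by construction", {
  res <- cost_registry(small_registry(seed = 3, n = 15))
  expect_equal(res$total_sd, res$baseline_sd + res$incremental_sd)
  expect_true(all(res$incremental_sd >= 0))
})

test_that("de-duplication counts shared interventions once", {
  reg <- manual_registry(rbind(
    rows_for_groups("a", packages = "1|2", value = 10, pin = 1e3, cov = 0.8),
    rows_for_groups("b", packages = "3", value = 5, pin = 1e3, cov = 0.8)),
    packages = data.frame(id = 1:4, name = default_package_names(4)))
  res <- cost_registry(reg)
  # unit 10 * pin 1e3 * 0.8 per group = 8e3; two groups.
  expect_equal(dedup_total(res, ids = "a"), 16e3)
  expect_equal(package_total(res, reg, 1), 16e3)
  expect_equal(package_total(res, reg, 2), 16e3)
  expect_equal(package_total(res, reg, 3), 8e3)
  # Shared intervention counted once in the dedup total, twice across packages.
  expect_equal(dedup_total(res), 24e3)
  expect_equal(sum(sapply(1:3, function(p) package_total(res, reg, p))), 40e3)
  expect_equal(package_total(res, reg, 4), 0)  # no members
  expect_equal(dedup_total(res, ids = character(0)), 0)
  expect_error(dedup_total(res, ids = "zzz"), class = "hbp_usage_error")
  expect_error(package_total(res, reg, 99), class = "hbp_usage_error")
})

test_that("markups convert service-delivery to grand totals", {
  expect_equal(apply_markups(100, markup_config(0, 0)),
               list(health_system = 0, grand_total = 100))
  mk <- apply_markups(100, markup_config(0.5, 0.25))
  expect_equal(mk$health_system, 75)
  expect_equal(mk$grand_total, 175)
  expect_equal(100 * mk$health_system / mk$grand_total, 42.857, tolerance = 1e-4)
  # Default calibrated markups: health-system share of the grand total.
  d <- apply_markups(1, markup_config())
  expect_equal(100 * d$health_system / d$grand_total, 42.8, tolerance = 0.05)
  expect_error(markup_config(-0.1, 0), class = "hbp_validation_error")
  expect_error(apply_markups(-1), class = "hbp_validation_error")
})

test_that("per-capita and %-GNI affordability metrics", {
  lic <- country_group("LIC", 0.90e9, 0.70e12)
  lmic <- country_group("lower-MIC", 2.7e9, 5.9e12)
  expect_equal(render_2sf(per_capita(71e9, lic)), 79)
  expect_equal(render_2sf(per_capita(350e9, lmic)), 130)
  expect_equal(per_capita(0, lic), 0)
  expect_equal(render_2sf(100 * share_of_gni(250e9, lmic)), 4.2)
  expect_equal(render_2sf(100 * share_of_gni(120e9, lmic)), 2.0)
  expect_equal(share_of_gni(0, lmic), 0)
  expect_error(per_capita(1, list(population = 0)), class = "hbp_validation_error")
  expect_error(share_of_gni(1, list(gni_total = 0)), class = "hbp_validation_error")
})

test_that("engine equals the brute-force summation oracle on random registries", {
  for (seed in 1:6) {
    n <- 3 + (seed * 3) %% 18  # registries of <= 20 interventions
    reg <- small_registry(seed = seed, n = n)
    summ <- cost_summary(reg)
    comb <- summ[summ$group == "combined", ]
    expect_equal(comb$grand_total, oracle_grand_total(reg), tolerance = 1e-10)
    expect_equal(comb$grand_incremental,
                 oracle_grand_total(reg, field = "incremental"), tolerance = 1e-10)
  }
})

test_that("monotonicity: incremental cost rises with target, falls with baseline", {
  reg <- small_registry(seed = 11, n = 12)
  incr_at <- function(target) {
    sum(cost_registry(reg, coverage_policy(target))$incremental_sd)
  }
  targets <- c(0.2, 0.5, 0.8, 0.95, 1)
  expect_true(all(diff(vapply(targets, incr_at, numeric(1))) >= 0))

  # Raising every baseline coverage never increases the increment.
  lift <- reg
  lift$interventions$baseline_coverage <-
    pmin(1, lift$interventions$baseline_coverage * 1.5)
  expect_lte(sum(cost_registry(lift)$incremental_sd),
             sum(cost_registry(reg)$incremental_sd))
})

test_that("homogeneity: scaling all unit costs by k scales every money output", {
  reg <- small_registry(seed = 5, n = 8)
  k <- 3.7
  scaled <- reg
  scaled$interventions$unit_cost_value <- scaled$interventions$unit_cost_value * k
  s1 <- cost_summary(reg)
  s2 <- cost_summary(scaled)
  money <- c("total_sd", "dedup_baseline_sd", "dedup_incremental_sd",
             "dedup_total_sd", "health_system", "grand_total",
             "total_per_capita", "incremental_pct_gni")
  for (col in money) expect_equal(s2[[col]], k * s1[[col]], tolerance = 1e-12)
})

test_that("conservation: dedup <= sum of package totals, equal iff disjoint", {
  overlapping <- small_registry(seed = 2, n = 15, overlap_rate = 0.8)
  res <- cost_registry(overlapping)
  pkg_sum <- sum(vapply(overlapping$packages$id, function(p) {
    package_total(res, overlapping, p)
  }, numeric(1)))
  expect_lt(dedup_total(res), pkg_sum)

  disjoint <- small_registry(seed = 2, n = 15, overlap_rate = 0)
  res_d <- cost_registry(disjoint)
  pkg_sum_d <- sum(vapply(disjoint$packages$id, function(p) {
    package_total(res_d, disjoint, p)
  }, numeric(1)))
  expect_equal(dedup_total(res_d), pkg_sum_d, tolerance = 1e-12)
})

test_that("the HPP is costed by the same engine on the subset", {
  reg <- small_registry(seed = 9, n = 10)
  all_res <- cost_registry(reg)
  hpp_res <- cost_registry(reg, hpp_only = TRUE)
  hpp_ids <- unique(reg$interventions$id[reg$interventions$hpp])
  expect_setequal(unique(hpp_res$id), hpp_ids)
  expect_equal(dedup_total(hpp_res), dedup_total(all_res, ids = hpp_ids))
})
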