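one_iv_registry <- function(cov = 0.8, pin = 1e6) {
  hbp_registry(base_row("a", "A", value = 1, pin = pin, cov = cov),
               country_group("A", 1e6, 1e9))
}

test_that("uncertain_param validates its range and fixes markup grouping", {
  p <- uncertain_param("unit_cost", 0.5, 1.5)
  expect_equal(p$point, 1)
  expect_error(uncertain_param("unit_cost", 1.5, 0.5),
               class = "hbp_validation_error")
  expect_error(uncertain_param("unit_cost", -1, 1),
               class = "hbp_validation_error")
  expect_error(uncertain_param("lognormal_what", 1, 2), "arg")
  expect_equal(uncertain_param("facility_markup", 0.5, 1.5,
                               grouping = "per_cell")$grouping, "global")
  expect_error(uncertain_param("unit_cost", 0, 2, family = "lognormal"),
               class = "hbp_validation_error")
})

test_that("one_way: null perturbation, family ranking, coverage monotonicity", {
  reg <- small_registry(seed = 8, n = 12)
  null <- one_way(reg, "unit_cost", 1, 1)
  expect_equal(null$swing, 0)

  # Unit cost +/-50% must out-swing population-in-need +/-10%.
  uc <- one_way(reg, "unit_cost", 0.5, 1.5)
  pin <- one_way(reg, "population_in_need", 0.9, 1.1)
  expect_gt(uc$swing, pin$swing)

  # Pushing baseline coverage up shrinks the incremental metric.
  cv <- one_way(reg, "baseline_coverage", 1, 1.8)
  expect_lt(cv$metric_high, cv$metric_low)

  expect_error(one_way(reg, "unit_cost", 0, 1), class = "hbp_validation_error")
  expect_error(one_way(reg, "not_a_family", 0.5, 1.5), "arg")
})

test_that("tornado orders families by swing and unit cost/coverage lead", {
  reg <- small_registry(seed = 8, n = 12)
  tor <- tornado(reg)
  expect_setequal(tor$parameter,
                  c("unit_cost", "baseline_coverage", "facility_markup",
                    "above_facility_markup", "population_in_need",
                    "fertility_proxy"))
  expect_true(all(diff(tor$swing) <= 0))
  expect_true(all(c("unit_cost", "baseline_coverage") %in% tor$parameter[1:3]))
})

test_that("point-mass distributions collapse the credible interval", {
  reg <- small_registry(seed = 6, n = 6)
  params <- list(uncertain_param("unit_cost", 1, 1),
                 uncertain_param("baseline_coverage", 1, 1),
                 uncertain_param("facility_markup", 1, 1))
  s <- run_psa(reg, params, psa_config(n_sims = 50, seed = 2))
  expect_equal(s$lo, s$point, tolerance = 1e-12)
  expect_equal(s$hi, s$point, tolerance = 1e-12)
})

test_that("PSA credible interval matches closed-form uniform quantiles", {
  # Single intervention, unit cost ~ Uniform(1, 3), pop 1e6, coverage fixed
  # at the 0.8 target: total cost = 0.8e6 * U, so the 95% CrI endpoints are
  # 0.8e6 * (1.05, 2.95).
  reg <- one_iv_registry(cov = 0.8)
  params <- list(uncertain_param("unit_cost", 1, 3, point = 2))
  s <- run_psa(reg, params, psa_config(n_sims = 10000, seed = 5),
               markups = markup_config(0, 0), metric = "total")
  expect_equal(s$point, 0.8e6 * 2)
  expect_equal(s$lo, 0.8e6 * 1.05, tolerance = 0.02)
  expect_equal(s$hi, 0.8e6 * 2.95, tolerance = 0.02)
  expect_lte(s$lo, s$hi)
})

test_that("fixed seed gives bit-identical PSA output; seeds differ draws", {
  reg <- small_registry(seed = 3, n = 8)
  cfg <- psa_config(n_sims = 300, seed = 11)
  a <- run_psa(reg, config = cfg, keep_draws = TRUE)
  b <- run_psa(reg, config = cfg, keep_draws = TRUE)
  expect_identical(a$draws, b$draws)
  expect_identical(c(a$point, a$lo, a$hi), c(b$point, b$lo, b$hi))
  c2 <- run_psa(reg, config = psa_config(n_sims = 300, seed = 12))
  expect_false(identical(c(a$lo, a$hi), c(c2$lo, c2$hi)))
})

test_that("parameter streams are independent and stable under extension", {
  reg <- one_iv_registry()
  p1 <- uncertain_param("unit_cost", 0.5, 1.5, grouping = "global")
  p2 <- uncertain_param("population_in_need", 0.8, 1.2, grouping = "global")
  cfg <- psa_config(n_sims = 4000, seed = 7)
  s12 <- run_psa(reg, list(p1, p2), cfg, keep_draws = TRUE)
  expect_lt(abs(stats::cor(s12$param_draws$unit_cost[, 1],
                           s12$param_draws$population_in_need[, 1])), 0.05)
  # Adding a parameter does not perturb the first parameter's draws.
  s1 <- run_psa(reg, list(p1), cfg, keep_draws = TRUE)
  expect_identical(s1$param_draws$unit_cost, s12$param_draws$unit_cost)
})

test_that("per-intervention grouping draws independently across interventions", {
  reg <- small_registry(seed = 10, n = 20)
  p <- uncertain_param("unit_cost", 0.5, 1.5, grouping = "per_intervention")
  s <- run_psa(reg, list(p), psa_config(n_sims = 2000, seed = 9),
               keep_draws = TRUE)
  d <- s$param_draws$unit_cost
  expect_equal(ncol(d), 20)
  expect_lt(abs(stats::cor(d[, 1], d[, 2])), 0.08)
  # Independent draws across many interventions tighten the aggregate CrI
  # relative to one shared multiplier.
  sg <- run_psa(reg, list(uncertain_param("unit_cost", 0.5, 1.5,
                                          grouping = "global")),
                psa_config(n_sims = 2000, seed = 9))
  expect_lt(s$hi / s$lo, sg$hi / sg$lo)
})

test_that("triangular and lognormal families respect their stated shapes", {
  reg <- one_iv_registry()
  tri <- run_psa(reg, list(uncertain_param("unit_cost", 0.5, 1.5,
                                           family = "triangular")),
                 psa_config(n_sims = 4000, seed = 13), keep_draws = TRUE,
                 markups = markup_config(0, 0), metric = "total")
  d <- tri$param_draws$unit_cost[, 1]
  expect_true(all(d >= 0.5 & d <= 1.5))
  expect_equal(mean(d), 1, tolerance = 0.02)  # symmetric triangle
  ln <- run_psa(reg, list(uncertain_param("unit_cost", 0.5, 2, point = 1,
                                          family = "lognormal")),
                psa_config(n_sims = 4000, seed = 14), keep_draws = TRUE)
  expect_equal(stats::median(ln$param_draws$unit_cost[, 1]), 1, tolerance = 0.05)
})
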