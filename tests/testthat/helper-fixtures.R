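# Fixtures are built in code; nothing is read from disk.

test_groups <- function() {
  rbind(country_group("A", 1e6, 1e9), country_group("B", 2e6, 4e9))
}

# One flat registry row with clean defaults: USD 2016 prices, fully traded
# inputs, per-patient-year basis, so unit_cost_py == value and engine
# arithmetic is exact by hand.
base_row <- function(id = "a", group = "A", packages = "1",
                     platform = "health_centre", timing = "chronic",
                     objective = "disability", hpp = TRUE, pathology = FALSE,
                     value = 10, currency = "USD", year = 2016, sgni = 1000,
                     basis = "per_patient_year", episodes = NA_real_,
                     traded = 1, pin = 1e5, cov = 0.3,
                     name = paste("intervention", id)) {
  data.frame(id = id, name = name, packages = packages, platform = platform,
             timing = timing, objective = objective, hpp = hpp,
             pathology = pathology, group = group, unit_cost_value = value,
             unit_cost_currency = currency, unit_cost_price_year = year,
             source_gni_per_capita = sgni, cost_basis = basis,
             episodes_per_beneficiary_year = episodes, traded_fraction = traded,
             population_in_need = pin, baseline_coverage = cov,
             stringsAsFactors = FALSE)
}

# One row per declared group, classification shared.
rows_for_groups <- function(id, groups = c("A", "B"), ...) {
  do.call(rbind, lapply(groups, function(g) base_row(id = id, group = g, ...)))
}

manual_registry <- function(tab, groups = test_groups(), packages = NULL,
                            check = TRUE) {
  hbp_registry(tab, groups, packages, check = check)
}

# Small random registry for property tests.
small_registry <- function(seed = 1, n = 10, overlap_rate = 0.3, ...) {
  generate_registry(seed = seed, n_interventions = n, n_packages = 4,
                    n_hpp = max(1, n %/% 2), overlap_rate = overlap_rate,
                    groups = test_groups(),
                    dimension_weights = list(
                      platform = setNames(rep(0.2, 5), hbp_platforms),
                      timing = setNames(rep(1 / 3, 3), hbp_timings),
                      objective = setNames(rep(0.2, 5), hbp_objectives[1:5])),
                    ...)
}

# Independent brute-force costing oracle: explicit per-row loop arithmetic,
# sharing no code with the engine's vectorised path. Returns the grand total
# (de-duplicated service delivery + markups) pooled over all groups.
oracle_grand_total <- function(registry, target = 0.8, facility = 0.45,
                               above = 0.298, field = "total") {
  series <- default_price_index()
  iv <- registry$interventions
  dedup <- 0
  for (r in seq_len(nrow(iv))) {
    fx <- series$fx$fx_rate[series$fx$currency == iv$unit_cost_currency[r] &
                              series$fx$year == iv$unit_cost_price_year[r]]
    idx <- series$index$index[series$index$year == iv$unit_cost_price_year[r]]
    usd <- iv$unit_cost_value[r] * fx / idx
    tgni <- registry$groups$gni_per_capita[registry$groups$id == iv$group[r]]
    moved <- usd * (iv$traded_fraction[r] +
                      (1 - iv$traded_fraction[r]) * tgni / iv$source_gni_per_capita[r])
    annual <- if (iv$cost_basis[r] == "per_episode") {
      moved * iv$episodes_per_beneficiary_year[r]
    } else moved
    cov <- iv$baseline_coverage[r]
    baseline <- annual * iv$population_in_need[r] * cov
    total <- annual * iv$population_in_need[r] * max(cov, target)
    dedup <- dedup + switch(field, total = total, baseline = baseline,
                            incremental = total - baseline)
  }
  dedup * (1 + facility + above)
}

registry_equal <- function(a, b) {
  ia <- a$interventions[order(a$interventions$id, a$interventions$group), ]
  ib <- b$interventions[order(b$interventions$id, b$interventions$group), ]
  rownames(ia) <- rownames(ib) <- NULL
  expect_equal(ia, ib, tolerance = 1e-12)
  expect_equal(a$groups[order(a$groups$id), c("id", "population", "gni_total")],
               b$groups[order(b$groups$id), c("id", "population", "gni_total")],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(a$packages[order(a$packages$id), ],
               b$packages[order(b$packages$id), ], ignore_attr = TRUE)
}
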