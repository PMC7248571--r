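Package: hbpcost
Title: Costing of Essential Health Benefits Packages in Stylised Country
    Income Groups
Version: 0.1.0
Authors@R:
    person("hbpcost", "maintainers", email = "maintainers@hbpcost.org",
           role = c("aut", "cre"))
Description: A counterfactual costing engine for essential universal health
    coverage (EUHC) benefits packages. Estimates baseline, incremental, and
    total annual service-delivery costs of a registry of health interventions
    at a target coverage (default 80%) in stylised low-income and
    lower-middle-income country groups, standardising study unit costs to
    2016 US dollars with traded/non-traded input transfer, de-duplicating
    overlapping package memberships, and applying facility and above-facility
    health-system markups. Costs are disaggregated by delivery platform,
    delivery timing, health-system objective, and package; one-way (tornado)
    and probabilistic (Monte Carlo) sensitivity analyses produce 95% credible
    intervals. A seeded synthetic registry generator emulates the structure
    of the 218-intervention EUHC package so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
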