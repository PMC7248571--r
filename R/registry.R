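# Domain types, validation, and tabular I/O for the intervention registry.
#
# A registry is stored flat: one row per (intervention, country group), with
# classification columns repeated on every row of an intervention. Flat files
# are the lingua franca of costing teams; the loader asserts classification
# consistency across a given intervention's rows.

#' Delivery platforms, timings, objectives, and cost bases
#'
#' Controlled vocabularies for intervention classification: five delivery
#' platforms (the physical/organisational channel), three delivery timing
#' classes (frequency and urgency of client-provider contact), five
#' health-system objectives plus `unallocated` (reserved for pathology-type
#' support interventions that do not fit any one objective), and two unit-cost
#' bases (chronic interventions are costed per patient-year, acute ones per
#' episode).
#'
#' @name vocabularies
#' @export
hbp_platforms <- c("population_based", "community", "health_centre",
                   "first_level_hospital", "referral_specialty_hospital")

#' @rdname vocabularies
#' @export
hbp_timings <- c("urgent", "chronic", "time_bound")

#' @rdname vocabularies
#' @export
hbp_objectives <- c("under5_mortality", "mortality_5_69_cmpn",
                    "mortality_5_69_ncdi", "disability", "non_health",
                    "unallocated")

#' @rdname vocabularies
#' @export
hbp_cost_bases <- c("per_patient_year", "per_episode")

#' Default names for the 21 essential intervention packages
#'
#' @param n number of packages (1-21).
#' @return character vector of package display names.
#' @export
default_package_names <- function(n = 21) {
  stopifnot(n >= 1, n <= 21)
  c("Maternal and newborn health",
    "Child health",
    "School-age health and development",
    "Adolescent health and development",
    "Reproductive health and contraception",
    "HIV and STIs",
    "Tuberculosis",
    "Malaria and adult febrile illness",
    "Neglected tropical diseases",
    "Pandemic and emergency preparedness",
    "Cardiovascular, respiratory, and related disorders",
    "Cancer",
    "Mental, neurological, and substance use disorders",
    "Musculoskeletal disorders",
    "Congenital and genetic disorders",
    "Injury prevention",
    "Environmental improvement",
    "Surgery",
    "Rehabilitation",
    "Palliative care and pain control",
    "Pathology")[seq_len(n)]
}

#' Construct a stylised country income group
#'
#' @param id group label, e.g. `"LIC"` or `"lower-MIC"`.
#' @param population persons (must be > 0).
#' @param gni_total gross national income, USD/year (must be > 0).
#' @return one-row data frame with derived `gni_per_capita`.
#' @export
country_group <- function(id, population, gni_total) {
  if (any(population <= 0)) stop_validation("population must be > 0")
  if (any(gni_total <= 0)) stop_validation("gni_total must be > 0")
  data.frame(id = as.character(id), population = as.numeric(population),
             gni_total = as.numeric(gni_total),
             gni_per_capita = as.numeric(gni_total) / as.numeric(population),
             stringsAsFactors = FALSE)
}

# Canonical column order of the flat intervention table.
registry_columns <- c(
  "id", "name", "packages", "platform", "timing", "objective", "hpp",
  "pathology", "group", "unit_cost_value", "unit_cost_currency",
  "unit_cost_price_year", "source_gni_per_capita", "cost_basis",
  "episodes_per_beneficiary_year", "traded_fraction", "population_in_need",
  "baseline_coverage")

#' Assemble a registry object
#'
#' @param interventions flat data frame, one row per (intervention, group);
#'   see `registry_columns` in the package source or the README schema.
#'   `packages` is a `|`-separated list of integer package ids.
#' @param groups data frame from [country_group()] (rows may be concatenated).
#' @param packages data frame with columns `id` (integer) and `name`;
#'   defaults to the standard 21 essential-package names covering all ids
#'   referenced by `interventions`.
#' @param check validate and stop on the first diagnostics (default `TRUE`).
#' @return an object of class `hbp_registry`.
#' @export
hbp_registry <- function(interventions, groups, packages = NULL, check = TRUE) {
  interventions <- as.data.frame(interventions, stringsAsFactors = FALSE)
  missing_cols <- setdiff(registry_columns, names(interventions))
  if (length(missing_cols) > 0) {
    stop_validation("registry table is missing columns: ",
                    paste(missing_cols, collapse = ", "))
  }
  interventions <- interventions[registry_columns]
  interventions$id <- as.character(interventions$id)
  interventions$group <- as.character(interventions$group)
  interventions$hpp <- as.logical(interventions$hpp)
  interventions$pathology <- as.logical(interventions$pathology)
  for (col in c("unit_cost_value", "unit_cost_price_year",
                "source_gni_per_capita", "episodes_per_beneficiary_year",
                "traded_fraction", "population_in_need", "baseline_coverage")) {
    interventions[[col]] <- as.numeric(interventions[[col]])
  }
  if (is.null(packages)) {
    ids <- referenced_package_ids(interventions$packages)
    n <- if (length(ids) > 0) max(ids) else 21L
    packages <- data.frame(id = seq_len(n),
                           name = default_package_names(n),
                           stringsAsFactors = FALSE)
  }
  packages <- as.data.frame(packages, stringsAsFactors = FALSE)
  packages$id <- as.integer(packages$id)
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  if (!"gni_per_capita" %in% names(groups)) {
    groups$gni_per_capita <- groups$gni_total / groups$population
  }
  reg <- structure(list(interventions = interventions, groups = groups,
                        packages = packages), class = "hbp_registry")
  if (check) {
    diag <- validate_registry(reg)
    if (nrow(diag) > 0) {
      stop_validation("invalid registry (", nrow(diag), " diagnostic(s)):\n",
                      paste(utils::head(diag$message, 10), collapse = "\n"))
    }
  }
  reg
}

#' @export
print.hbp_registry <- function(x, ...) {
  cat(sprintf("<hbp_registry> %d interventions x %d groups, %d packages, %d HPP\n",
              length(unique(x$interventions$id)), nrow(x$groups),
              nrow(x$packages),
              length(unique(x$interventions$id[x$interventions$hpp]))))
  invisible(x)
}

parse_package_ids <- function(s) {
  lapply(strsplit(as.character(s), "|", fixed = TRUE), function(p) {
    p <- p[nzchar(trimws(p))]
    as.integer(trimws(p))
  })
}

referenced_package_ids <- function(s) {
  sort(unique(unlist(parse_package_ids(s))))
}

#' Number of unique interventions in a registry
#' @param registry an `hbp_registry`.
#' @return integer count.
#' @export
n_interventions <- function(registry) {
  length(unique(registry$interventions$id))
}

#' Validate a registry
#'
#' Checks every type invariant and returns diagnostics instead of raising:
#' one row per violation, naming the offending row, intervention, and field.
#'
#' @param registry an `hbp_registry` (checks are safe on malformed input).
#' @return data frame with columns `row`, `id`, `group`, `field`, `message`;
#'   zero rows iff the registry is valid.
#' @export
validate_registry <- function(registry) {
  out <- list()
  add <- function(row, id, group, field, message) {
    out[[length(out) + 1]] <<- data.frame(
      row = as.integer(row), id = as.character(id), group = as.character(group),
      field = field, message = message, stringsAsFactors = FALSE)
  }
  iv <- registry$interventions
  grp <- registry$groups
  pkg <- registry$packages

  if (is.null(iv) || nrow(iv) == 0) {
    add(NA, NA, NA, "interventions", "registry has no interventions")
    return(do.call(rbind, out))
  }

  # Country-group invariants.
  for (g in seq_len(nrow(grp))) {
    if (!isTRUE(grp$population[g] > 0)) {
      add(g, grp$id[g], grp$id[g], "population",
          sprintf("group '%s': population must be > 0", grp$id[g]))
    }
    if (!isTRUE(grp$gni_total[g] > 0)) {
      add(g, grp$id[g], grp$id[g], "gni_total",
          sprintf("group '%s': gni_total must be > 0", grp$id[g]))
    }
    if (isTRUE(grp$population[g] > 0) && isTRUE(grp$gni_total[g] > 0)) {
      expect <- grp$gni_total[g] / grp$population[g]
      if (abs(grp$gni_per_capita[g] - expect) > 1e-9 * expect) {
        add(g, grp$id[g], grp$id[g], "gni_per_capita",
            sprintf("group '%s': gni_per_capita inconsistent with gni_total/population",
                    grp$id[g]))
      }
    }
  }

  # Row-level invariants.
  pkg_lists <- parse_package_ids(iv$packages)
  for (r in seq_len(nrow(iv))) {
    id <- iv$id[r]; g <- iv$group[r]
    where <- sprintf("row %d (intervention '%s', group '%s')", r, id, g)
    pks <- pkg_lists[[r]]
    if (length(pks) == 0 || anyNA(pks)) {
      add(r, id, g, "packages", paste0(where, ": packages must be a non-empty list of ids"))
    } else if (!all(pks %in% pkg$id)) {
      add(r, id, g, "packages",
          paste0(where, ": unknown package id(s) ",
                 paste(setdiff(pks, pkg$id), collapse = ", ")))
    }
    if (!iv$platform[r] %in% hbp_platforms) {
      add(r, id, g, "platform", paste0(where, ": invalid platform '", iv$platform[r], "'"))
    }
    if (!iv$timing[r] %in% hbp_timings) {
      add(r, id, g, "timing", paste0(where, ": invalid timing '", iv$timing[r], "'"))
    }
    if (!iv$objective[r] %in% hbp_objectives) {
      add(r, id, g, "objective", paste0(where, ": invalid objective '", iv$objective[r], "'"))
    } else if (iv$objective[r] == "unallocated" && !isTRUE(iv$pathology[r])) {
      add(r, id, g, "objective",
          paste0(where, ": objective 'unallocated' is reserved for pathology-flagged interventions"))
    }
    if (is.na(iv$hpp[r])) add(r, id, g, "hpp", paste0(where, ": hpp flag must be TRUE/FALSE"))
    if (is.na(iv$baseline_coverage[r]) || iv$baseline_coverage[r] < 0 ||
        iv$baseline_coverage[r] > 1) {
      add(r, id, g, "baseline_coverage",
          paste0(where, ": baseline_coverage must be in [0, 1]"))
    }
    if (is.na(iv$traded_fraction[r]) || iv$traded_fraction[r] < 0 ||
        iv$traded_fraction[r] > 1) {
      add(r, id, g, "traded_fraction", paste0(where, ": traded_fraction must be in [0, 1]"))
    }
    if (is.na(iv$population_in_need[r]) || iv$population_in_need[r] < 0) {
      add(r, id, g, "population_in_need",
          paste0(where, ": population_in_need must be >= 0"))
    }
    if (is.na(iv$unit_cost_value[r]) || iv$unit_cost_value[r] < 0) {
      add(r, id, g, "unit_cost_value", paste0(where, ": unit cost value must be >= 0"))
    }
    if (is.na(iv$unit_cost_price_year[r]) || iv$unit_cost_price_year[r] < 1990 ||
        iv$unit_cost_price_year[r] > 2016) {
      add(r, id, g, "unit_cost_price_year",
          paste0(where, ": price_year must be in [1990, 2016]"))
    }
    if (is.na(iv$source_gni_per_capita[r]) || iv$source_gni_per_capita[r] <= 0) {
      add(r, id, g, "source_gni_per_capita",
          paste0(where, ": source_gni_per_capita must be > 0"))
    }
    if (!iv$cost_basis[r] %in% hbp_cost_bases) {
      add(r, id, g, "cost_basis", paste0(where, ": invalid cost_basis '", iv$cost_basis[r], "'"))
    } else if (iv$cost_basis[r] == "per_episode" &&
               (is.na(iv$episodes_per_beneficiary_year[r]) ||
                iv$episodes_per_beneficiary_year[r] <= 0)) {
      add(r, id, g, "episodes_per_beneficiary_year",
          paste0(where, ": per_episode costs require episodes_per_beneficiary_year > 0"))
    }
  }

  # Cross-row invariants: duplicate (id, group), complete group coverage,
  # classification consistency across an intervention's rows.
  key <- paste(iv$id, iv$group, sep = "\r")
  dup <- duplicated(key)
  for (r in which(dup)) {
    add(r, iv$id[r], iv$group[r], "id",
        sprintf("duplicate intervention id '%s' for group '%s'", iv$id[r], iv$group[r]))
  }
  class_cols <- c("name", "packages", "platform", "timing", "objective",
                  "hpp", "pathology")
  for (id in unique(iv$id)) {
    rows <- which(iv$id == id)
    missing_groups <- setdiff(grp$id, iv$group[rows])
    for (mg in missing_groups) {
      add(rows[1], id, mg, "group",
          sprintf("intervention '%s' has no record for group '%s'", id, mg))
    }
    if (length(rows) > 1) {
      for (col in class_cols) {
        if (length(unique(iv[[col]][rows])) > 1) {
          add(rows[1], id, NA, col,
              sprintf("intervention '%s': classification column '%s' differs across group rows",
                      id, col))
        }
      }
    }
  }

  if (length(out) == 0) {
    return(data.frame(row = integer(), id = character(), group = character(),
                      field = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

companion_path <- function(path, suffix) {
  paste0(tools::file_path_sans_ext(path), "_", suffix, ".csv")
}

#' Load an intervention registry from disk
#'
#' CSV registries are a file trio: the flat intervention table at `path`, a
#' group table (`id`, `population`, `gni_total`), and a package table (`id`,
#' `name`). Companion files default to `<path>_groups.csv` and
#' `<path>_packages.csv`. JSON registries embed all three tables in one file.
#'
#' @param path registry file.
#' @param format `"csv"` or `"json"` (default: inferred from the extension).
#' @param groups_path,packages_path optional explicit companion CSV paths.
#' @param check validate and raise on diagnostics (default `TRUE`).
#' @return an `hbp_registry`.
#' @export
load_registry <- function(path, format = NULL, groups_path = NULL,
                          packages_path = NULL, check = TRUE) {
  if (!file.exists(path)) stop_usage("registry file not found: ", path)
  format <- format %||% if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "json") {
    obj <- jsonlite::fromJSON(path)
    interventions <- as.data.frame(obj$interventions, stringsAsFactors = FALSE)
    groups <- as.data.frame(obj$groups, stringsAsFactors = FALSE)
    packages <- as.data.frame(obj$packages, stringsAsFactors = FALSE)
  } else {
    interventions <- utils::read.csv(path, stringsAsFactors = FALSE,
                                     colClasses = c(id = "character"),
                                     encoding = "UTF-8")
    gp <- groups_path %||% companion_path(path, "groups")
    if (!file.exists(gp)) stop_usage("groups file not found: ", gp)
    groups <- utils::read.csv(gp, stringsAsFactors = FALSE, encoding = "UTF-8")
    pp <- packages_path %||% companion_path(path, "packages")
    packages <- if (file.exists(pp)) {
      utils::read.csv(pp, stringsAsFactors = FALSE, encoding = "UTF-8")
    } else NULL
  }
  if (nrow(interventions) == 0) stop_validation("registry has no interventions")
  hbp_registry(interventions, groups, packages, check = check)
}

#' Write a registry to disk
#'
#' Inverse of [load_registry()]: `load_registry(write_registry(r, p))` equals
#' `r` field for field. CSV output writes the `_groups.csv` / `_packages.csv`
#' companions next to `path`.
#'
#' @param registry an `hbp_registry`.
#' @param path output file.
#' @param format `"csv"` or `"json"` (default: inferred from the extension).
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "json") {
    jsonlite::write_json(
      list(groups = registry$groups[c("id", "population", "gni_total")],
           packages = registry$packages,
           interventions = registry$interventions),
      path, dataframe = "rows", digits = NA, auto_unbox = FALSE, pretty = TRUE)
  } else {
    utils::write.csv(registry$interventions, path, row.names = FALSE,
                     fileEncoding = "UTF-8")
    utils::write.csv(registry$groups[c("id", "population", "gni_total")],
                     companion_path(path, "groups"), row.names = FALSE,
                     fileEncoding = "UTF-8")
    utils::write.csv(registry$packages, companion_path(path, "packages"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
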