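#' Apply a case-definition algorithm to one person's claims
#'
#' Scans candidate anchor claims in ascending date order. The definition is
#' satisfied at an anchor if, within the observation window of
#' `window_years * 365 - 1` days starting at the anchor, there are at least
#' `min_hospital` hospital claims (when hospital records are used) or at
#' least `min_physician` physician claims, the latter counted after greedy
#' 30-day spacing when the spacing rule applies. The case date is the
#' earliest satisfying anchor; the case is incident when no disease claim of
#' any setting occurs in the `lookback_years * 365` days before the case date.
#'
#' @param claims data.frame for one person with columns `service_date`
#'   (Date) and `setting`, already filtered to disease codes within coverage
#'   and sorted by date (hospital before physician on ties).
#' @param spec an `algorithm_spec`.
#' @param lookback_years diagnosis-free lookback defining incidence (3).
#' @return `NULL` if the person never satisfies the definition, else a list
#'   with `case_date` and `incident`.
#' @export
ascertain_person <- function(claims, spec, lookback_years = 3L) {
  d <- as.numeric(claims$service_date)
  ascertain_vec(d, claims$setting == "hospital", spec, lookback_years)
}

# Hot path shared by ascertain_person()/ascertain_cases(): dates as numeric
# days, settings as a hospital indicator.
ascertain_vec <- function(d, is_hosp, spec, lookback_years = 3L) {
  n <- length(d)
  if (n == 0L) {
    return(NULL)
  }
  if (is.unsorted(d)) stop("claims must be pre-sorted by service date")
  hosp <- d[is_hosp]
  phys <- d[!is_hosp]
  window_days <- spec$window_years * 365L - 1L
  spaced <- spec$min_days_apart > 0L
  for (i in seq_len(n)) {
    a <- d[i]
    wend <- a + window_days
    if (spec$min_hospital > 0L &&
      sum(hosp >= a & hosp <= wend) >= spec$min_hospital) {
      return(make_case(a, d, lookback_years))
    }
    p <- phys[phys >= a & phys <= wend]
    if (length(p) >= spec$min_physician) {
      cnt <- if (spaced) count_spaced(p, spec$min_days_apart) else length(p)
      if (cnt >= spec$min_physician) {
        return(make_case(a, d, lookback_years))
      }
    }
  }
  NULL
}

# greedy earliest-first count of dates >= gap apart (numeric days)
count_spaced <- function(d, gap) {
  cnt <- 1L
  last <- d[1]
  for (i in seq_along(d)[-1]) {
    if (d[i] - last >= gap) {
      cnt <- cnt + 1L
      last <- d[i]
    }
  }
  cnt
}

make_case <- function(anchor, all_dates, lookback_years) {
  lb <- lookback_years * 365L
  incident <- !any(all_dates >= anchor - lb & all_dates < anchor)
  list(case_date = as.Date(anchor, origin = "1970-01-01"), incident = incident)
}

# Disease claims filtered to coverage and sorted for ascertainment.
disease_claims <- function(registry, claims) {
  cl <- data.table::as.data.table(claims)
  cl <- cl[is_diabetes_code(code, icd_version)]
  if (nrow(cl) == 0L) {
    return(cl[, .(person_id, service_date, setting)])
  }
  spells <- data.table::as.data.table(registry$spells)
  cl[, row_id := .I]
  covered <- spells[cl,
    on = .(person_id, spell_start <= service_date, spell_end >= service_date),
    nomatch = NULL, .(row_id = i.row_id)
  ]
  cl <- cl[row_id %in% covered$row_id]
  # hospital sorts before physician on equal dates (deterministic anchors)
  cl[, setting_rank := data.table::fifelse(setting == "hospital", 0L, 1L)]
  data.table::setorder(cl, person_id, service_date, setting_rank)
  cl[, .(person_id, service_date, setting)]
}

#' Ascertain cases for every person in a registry
#'
#' Filters claims to disease codes within coverage, then applies
#' [ascertain_person()] to each person.
#'
#' @param registry a `registry`.
#' @param claims claims data.frame (person_id, service_date, setting, code,
#'   icd_version).
#' @param spec an `algorithm_spec` or algorithm name.
#' @param lookback_years diagnosis-free lookback defining incidence.
#' @return data.frame with `person_id`, `case_date`, `incident`.
#' @export
ascertain_cases <- function(registry, claims, spec, lookback_years = 3L) {
  if (is.character(spec)) spec <- parse_algorithm_name(spec)
  dz <- disease_claims(registry, claims)
  ascertain_from_dz(dz, spec, lookback_years)
}

ascertain_from_dz <- function(dz, spec, lookback_years = 3L) {
  if (nrow(dz) == 0L) {
    return(data.frame(
      person_id = character(0), case_date = as.Date(character(0)),
      incident = logical(0)
    ))
  }
  dnum <- as.numeric(dz$service_date)
  hflag <- dz$setting == "hospital"
  res <- dz[, {
    r <- ascertain_vec(dnum[.I], hflag[.I], spec, lookback_years)
    if (is.null(r)) {
      list(case_date = as.Date(NA), incident = NA)
    } else {
      list(case_date = r$case_date, incident = r$incident)
    }
  }, by = person_id]
  as.data.frame(res[!is.na(case_date)])
}

# Shared per-dataset work reused across the 18 algorithms: the disease
# claims (filtered, coverage-clipped, sorted) and window-specific cohort
# grids, memoised in an environment.
study_cache <- function(registry, claims) {
  e <- new.env(parent = emptyenv())
  e$dz <- disease_claims(registry, claims)
  e$cohorts <- list()
  e
}

# Cohort person-years for a given observation window: person is in the
# year-Y cohort when continuously covered from Jan 1 of (Y - w + 1) through
# Dec 31 of Y by a single spell, and aged 0-17 at mid-year of Y.
cohort_grid <- function(registry, study_span, window_years) {
  spells <- data.table::as.data.table(registry$spells)
  if (nrow(spells) == 0L) stop("empty registry")
  fy <- full_year_bounds(spells)
  # windowed: the year-Y cohort needs w full years of coverage ending in Y
  yw0 <- pmax(fy$y0 + window_years - 1L, study_span[1])
  yw1 <- pmin(fy$y1, study_span[2])
  grid <- expand_years(spells$person_id, yw0, yw1)
  persons <- data.table::as.data.table(registry$persons)
  grid <- persons[grid, on = "person_id"]
  grid[, age := age_at_midyear(birth_date, year)]
  grid <- grid[age >= 0L & age <= 17L]
  grid[, group := age_group(age)]
  grid[, .(person_id, year, sex, group)]
}

#' Build incident and prevalent stratum count tables
#'
#' Aggregates ascertained cases into year x age-group x sex cells over the
#' study span. The year-Y cohort comprises persons continuously covered over
#' the algorithm's observation window ending Dec 31 of Y and aged 0--17 at
#' mid-year. Incident cells count cohort members whose incident case date
#' falls in year Y; prevalent cells count cohort members with a case date on
#' or before Dec 31 of Y. Cells with counts of 1--5 are flagged suppressed.
#'
#' @param registry a `registry`.
#' @param claims claims data.frame.
#' @param spec an `algorithm_spec` or algorithm name.
#' @param study_span `(first_year, last_year)` of the study (e.g. 1975--2016).
#' @param lookback_years diagnosis-free lookback defining incidence.
#' @param cache optional [study_cache()]-style environment reusing filtered
#'   claims and cohort grids across algorithms.
#' @return list with `incident` and `prevalent`, each a `count_table`
#'   data.frame (year, age_group, sex, case_count, cohort_size, suppressed)
#'   with attributes `algorithm` and `outcome`.
#' @export
build_count_tables <- function(registry, claims, spec, study_span,
                               lookback_years = 3L, cache = NULL) {
  if (is.character(spec)) spec <- parse_algorithm_name(spec)
  if (is.null(registry$persons) || nrow(registry$persons) == 0L) {
    stop("empty registry")
  }
  study_span <- as.integer(study_span)
  if (is.null(cache)) cache <- study_cache(registry, claims)
  cases <- data.table::as.data.table(
    ascertain_from_dz(cache$dz, spec, lookback_years)
  )
  wkey <- as.character(spec$window_years)
  if (is.null(cache$cohorts[[wkey]])) {
    cache$cohorts[[wkey]] <- cohort_grid(registry, study_span, spec$window_years)
  }
  grid <- cache$cohorts[[wkey]]
  cohort <- grid[, .(cohort_size = .N), by = .(year, age_group = as.character(group), sex)]

  if (nrow(cases) > 0L) {
    g <- merge(grid, cases, by = "person_id")
    inc <- g[incident == TRUE & data.table::year(case_date) == year]
    prev <- g[as.numeric(case_date) <= as.numeric(year_end(year))]
  } else {
    inc <- prev <- grid[0][, `:=`(case_date = as.Date(NA), incident = NA)]
  }
  list(
    incident = finish_count_table(inc, cohort, study_span, spec$name, "incidence"),
    prevalent = finish_count_table(prev, cohort, study_span, spec$name, "prevalence")
  )
}

finish_count_table <- function(case_rows, cohort, study_span, algorithm, outcome) {
  full <- data.table::CJ(
    year = seq.int(study_span[1], study_span[2]),
    age_group = c("0-9", "10-17"), sex = c("F", "M")
  )
  if (nrow(case_rows) > 0L) {
    counts <- case_rows[, .(case_count = .N),
      by = .(year, age_group = as.character(group), sex)
    ]
    full <- counts[full, on = c("year", "age_group", "sex")]
  } else {
    full[, case_count := 0L]
  }
  full[is.na(case_count), case_count := 0L]
  full <- cohort[full, on = c("year", "age_group", "sex")]
  full[is.na(cohort_size), cohort_size := 0L]
  full[, suppressed := case_count > 0L & case_count < 6L]
  data.table::setorder(full, year, age_group, sex)
  out <- as.data.frame(full[, .(year, age_group, sex, case_count, cohort_size, suppressed)])
  structure(out,
    class = c("count_table", "data.frame"),
    algorithm = algorithm, outcome = outcome, study_span = study_span
  )
}

#' Suppress small cells and impute or exclude
#'
#' Cells with counts of 1--5 are suppressed for privacy. If more than 10% of
#' cells are suppressed the table is excluded from modelling; otherwise each
#' suppressed count is replaced by an independent uniform draw from 1--5.
#'
#' @param table a `count_table`.
#' @param seed integer seed for the imputation draws.
#' @return list with `table` (imputed counts in `case_count`, originals in
#'   `observed_count`), `excluded` (logical) and `suppressed_fraction`.
#' @export
apply_suppression_and_imputation <- function(table, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  sup <- table$case_count > 0L & table$case_count < 6L
  table$suppressed <- sup
  frac <- mean(sup)
  table$observed_count <- table$case_count
  if (frac > 0.10) {
    return(list(table = table, excluded = TRUE, suppressed_fraction = frac))
  }
  if (any(sup)) {
    table$case_count[sup] <- with_stream(
      seed, paste("impute", attr(table, "algorithm"), attr(table, "outcome")),
      sample(1:5, sum(sup), replace = TRUE)
    )
  }
  list(table = table, excluded = FALSE, suppressed_fraction = frac)
}

#' @export
print.count_table <- function(x, ...) {
  cat(
    "<count_table>", attr(x, "outcome"), "for", attr(x, "algorithm"), "-",
    nrow(x), "cells,", sum(x$case_count), "cases,",
    sum(x$suppressed), "suppressed\n"
  )
  invisible(x)
}
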