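#' Configuration for the synthetic claims generator
#'
#' Defines the study conditions for a simulated paediatric chronic-disease
#' surveillance setting: a population of children observed over a multi-decade
#' span, a smooth secular trend in disease onset, per-case care-seeking
#' intensity, a diagnosis-coding process with imperfect sensitivity, and
#' optional coding-disruption events at known calendar years.
#'
#' @param n_persons number of persons in the registry.
#' @param span `(first_year, last_year)` of the simulation. The default starts
#'   in 1965, a decade before a typical 1975 study start, so the prevalent
#'   pool is largely burned in and a 3-year diagnosis-free lookback is
#'   available from the first study year.
#' @param incidence_hazard function `year -> annual onset probability` for a
#'   susceptible (covered, disease-free, aged 0--17) person-year. The default
#'   rises smoothly from 2.4 to 4.8 per 1,000 across 1975--2016.
#' @param visit_rate mean physician disease-related visits per case-year.
#' @param hosp_rate mean disease-related hospitalizations per case-year.
#' @param coding_sensitivity probability that a disease-related contact
#'   receives a disease diagnosis code (otherwise it is coded as an
#'   unrelated background contact).
#' @param background_rate,background_hosp_rate mean non-disease physician
#'   visits and hospitalizations per covered person-year (all persons).
#' @param gap_prob probability that a person's coverage has one gap
#'   (30--365 days) at a uniform time, splitting it into two spells.
#' @param disruptions list of [disruption_event()] objects.
#' @param seed master seed; every sub-process draws from its own named
#'   stream derived from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_persons = 60000L,
                       span = c(1965L, 2016L),
                       incidence_hazard = NULL,
                       visit_rate = 1.5,
                       hosp_rate = 0.2,
                       coding_sensitivity = 0.8,
                       background_rate = 0.2,
                       background_hosp_rate = 0.02,
                       gap_prob = 0.05,
                       disruptions = list(),
                       seed = 1L) {
  if (is.null(incidence_hazard)) {
    incidence_hazard <- function(year) {
      0.0024 + 0.0024 * pmin(pmax((year - 1975) / (2016 - 1975), 0), 1)
    }
  }
  cfg <- list(
    n_persons = as.integer(n_persons), span = as.integer(span),
    incidence_hazard = incidence_hazard, visit_rate = visit_rate,
    hosp_rate = hosp_rate, coding_sensitivity = coding_sensitivity,
    background_rate = background_rate,
    background_hosp_rate = background_hosp_rate,
    gap_prob = gap_prob, disruptions = disruptions, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_persons < 0) stop("n_persons must be non-negative")
  if (length(cfg$span) != 2 || cfg$span[1] > cfg$span[2]) {
    stop("span must be (first_year, last_year) with first_year <= last_year")
  }
  probs <- cfg$incidence_hazard(seq(cfg$span[1], cfg$span[2]))
  if (any(probs < 0 | probs > 1)) stop("incidence_hazard must lie in [0, 1]")
  if (cfg$coding_sensitivity < 0 || cfg$coding_sensitivity > 1) {
    stop("coding_sensitivity must lie in [0, 1]")
  }
  if (cfg$gap_prob < 0 || cfg$gap_prob > 1) stop("gap_prob must lie in [0, 1]")
  rates <- c(cfg$visit_rate, cfg$hosp_rate, cfg$background_rate, cfg$background_hosp_rate)
  if (any(rates < 0)) stop("rates must be non-negative")
  for (d in cfg$disruptions) {
    if (!inherits(d, "disruption_event")) stop("disruptions must be disruption_event objects")
    if (any(d$years < cfg$span[1] | d$years > cfg$span[2])) {
      stop("disruption years must lie within the simulation span")
    }
  }
  invisible(cfg)
}

#' A coding-disruption event
#'
#' Multiplies one generative parameter (coding sensitivity, physician visit
#' rate, or hospitalization rate) by a constant in the listed calendar years,
#' emulating an abrupt change in coding or care-seeking such as an ICD-version
#' switch.
#'
#' @param years calendar years affected.
#' @param target one of `"coding_sensitivity"`, `"visit_rate"`, `"hosp_rate"`.
#' @param multiplier non-negative multiplier applied in those years.
#' @export
disruption_event <- function(years, target = c("coding_sensitivity", "visit_rate", "hosp_rate"),
                             multiplier = 0.5) {
  target <- match.arg(target)
  if (multiplier < 0) stop("multiplier must be non-negative")
  structure(list(years = as.integer(years), target = target, multiplier = multiplier),
    class = "disruption_event"
  )
}

# Per-year effective value of a parameter after applying disruption events.
effective_param <- function(cfg, target, years) {
  base <- switch(target,
    coding_sensitivity = cfg$coding_sensitivity,
    visit_rate = cfg$visit_rate,
    hosp_rate = cfg$hosp_rate,
    stop("unknown disruption target: ", target)
  )
  out <- rep(base, length(years))
  for (d in cfg$disruptions) {
    if (d$target == target) out[years %in% d$years] <- out[years %in% d$years] * d$multiplier
  }
  out
}

#' Generate a synthetic person registry
#'
#' Persons are born uniformly over a window chosen so each is aged 0--17 for
#' at least part of the simulation span; sex is balanced; health-insurance
#' coverage runs from birth (or span start) until the 18th birthday (or span
#' end), with a single 30--365 day gap inserted with probability `gap_prob`.
#'
#' @param config a [sim_config()].
#' @return a `registry` object: list of `persons` (person_id, sex, birth_date)
#'   and `spells` (person_id, spell_start, spell_end).
#' @export
generate_population <- function(config) {
  validate_sim_config(config)
  with_stream(config$seed, "population", {
    n <- config$n_persons
    span <- config$span
    if (n == 0L) {
      persons <- data.frame(
        person_id = character(0), sex = character(0),
        birth_date = as.Date(character(0))
      )
      spells <- data.frame(
        person_id = character(0),
        spell_start = as.Date(character(0)), spell_end = as.Date(character(0))
      )
      return(structure(list(persons = persons, spells = spells), class = "registry"))
    }
    b0 <- as.numeric(year_start(span[1] - 17L))
    b1 <- as.numeric(year_end(span[2]))
    birth <- as.Date(floor(runif(n, b0, b1 + 1)), origin = "1970-01-01")
    sex <- sample(c("F", "M"), n, replace = TRUE)
    person_id <- sprintf("P%06d", seq_len(n))

    cov_start <- pmax(birth, year_start(span[1]))
    # coverage ends the day before the 18th birthday or at span end
    bday18 <- birth + round(18 * 365.25)
    cov_end <- pmin(bday18 - 1, year_end(span[2]))
    keep <- cov_end >= cov_start
    cov_start <- cov_start[keep]
    cov_end <- cov_end[keep]
    pid <- person_id[keep]

    has_gap <- runif(length(pid)) < config$gap_prob
    len <- as.numeric(cov_end - cov_start) + 1
    gap_at <- cov_start + floor(runif(length(pid)) * len)
    gap_len <- floor(runif(length(pid), 30, 366))

    first_end <- ifelse(has_gap, pmin(gap_at - 1, cov_end), cov_end)
    second_start <- gap_at + gap_len
    spells <- data.frame(
      person_id = pid, spell_start = cov_start,
      spell_end = as.Date(first_end, origin = "1970-01-01")
    )
    add <- has_gap & second_start <= cov_end
    if (any(add)) {
      spells <- rbind(spells, data.frame(
        person_id = pid[add],
        spell_start = as.Date(second_start[add], origin = "1970-01-01"),
        spell_end = cov_end[add]
      ))
    }
    spells <- spells[spells$spell_end >= spells$spell_start, , drop = FALSE]
    spells <- spells[order(spells$person_id, spells$spell_start), , drop = FALSE]
    rownames(spells) <- NULL
    persons <- data.frame(person_id = person_id, sex = sex, birth_date = birth)
    structure(list(persons = persons, spells = spells), class = "registry")
  })
}

#' @export
print.registry <- function(x, ...) {
  cat(
    "<registry>", nrow(x$persons), "persons,", nrow(x$spells),
    "coverage spells\n"
  )
  invisible(x)
}

# Person-year eligibility grid: years in which a person is aged 0-17 at
# mid-year and continuously covered from Jan 1 to Dec 31. data.table with
# person_id, year, sex, birth_date, age, group.
eligibility_grid <- function(registry, span) {
  spells <- data.table::as.data.table(registry$spells)
  if (nrow(spells) == 0L) {
    return(data.table::data.table(
      person_id = character(0), year = integer(0), sex = character(0),
      birth_date = as.Date(character(0)), age = integer(0),
      group = factor(character(0), levels = c("0-9", "10-17"))
    ))
  }
  y0 <- pmax(full_year_bounds(spells)$y0, span[1])
  y1 <- pmin(full_year_bounds(spells)$y1, span[2])
  grid <- expand_years(spells$person_id, y0, y1)
  persons <- data.table::as.data.table(registry$persons)
  grid <- persons[grid, on = "person_id"]
  grid[, age := age_at_midyear(birth_date, year)]
  grid <- grid[age >= 0L & age <= 17L]
  grid[, group := age_group(age)]
  data.table::setorder(grid, person_id, year)
  grid[]
}

#' Simulate disease onsets with known ground truth
#'
#' Each susceptible person-year (covered the full calendar year, aged 0--17
#' at mid-year, no previous onset) draws disease onset with probability
#' `incidence_hazard(year)`. Disease is absorbing: once onset occurs the
#' person remains a prevalent case while covered and aged under 18. Onset
#' dates are uniform within the onset year (before the 18th birthday).
#'
#' @param population a `registry` from [generate_population()].
#' @param config the [sim_config()] used to generate it.
#' @return a `ground_truth` object: `onsets` (person_id, onset_date),
#'   `incident` and `prevalent` stratum count tables keyed by
#'   (year, age_group, sex), and the internal eligibility grid.
#' @export
simulate_onsets <- function(population, config) {
  validate_sim_config(config)
  grid <- eligibility_grid(population, config$span)
  with_stream(config$seed, "onsets", {
    p <- config$incidence_hazard(grid$year)
    if (any(p < 0 | p > 1)) stop("incidence_hazard must lie in [0, 1]")
    hit <- runif(nrow(grid)) < p
    onset_rows <- if (any(hit)) {
      grid[hit, .(year = min(year)), by = person_id]
    } else {
      data.table::data.table(person_id = character(0), year = integer(0))
    }
    onsets <- merge(onset_rows,
      data.table::as.data.table(population$persons)[, .(person_id, birth_date)],
      by = "person_id"
    )
    d0 <- as.numeric(year_start(onsets$year))
    d1 <- as.numeric(pmin(
      year_end(onsets$year),
      onsets$birth_date + round(18 * 365.25) - 1
    ))
    onsets[, onset_date := as.Date(floor(runif(.N, d0, d1 + 1)), origin = "1970-01-01")]
    onsets[, birth_date := NULL]
    data.table::setnames(onsets, "year", "onset_year")
    data.table::setorder(onsets, person_id)

    g <- merge(grid, onsets, by = "person_id", all.x = TRUE)
    incident <- tabulate_strata(g[!is.na(onset_year) & year == onset_year], config$span)
    prevalent <- tabulate_strata(g[!is.na(onset_year) & year >= onset_year], config$span)
    structure(
      list(
        onsets = as.data.frame(onsets), incident = incident,
        prevalent = prevalent, grid = g
      ),
      class = "ground_truth"
    )
  })
}

tabulate_strata <- function(dt, span) {
  full <- data.table::CJ(
    year = seq.int(span[1], span[2]),
    age_group = c("0-9", "10-17"), sex = c("F", "M")
  )
  if (nrow(dt) == 0L) {
    full[, count := 0L]
  } else {
    counts <- dt[, .(count = .N), by = .(year, age_group = as.character(group), sex)]
    full <- counts[full, on = c("year", "age_group", "sex")]
    full[is.na(count), count := 0L]
  }
  data.table::setorder(full, year, age_group, sex)
  as.data.frame(full)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", nrow(x$onsets), "onsets;",
    sum(x$incident$count), "eligible incident person-years\n")
  invisible(x)
}

#' Simulate coded healthcare claims
#'
#' Every case person-year generates a diagnostic physician contact on the
#' onset date plus Poisson-distributed follow-up physician visits and
#' hospitalizations; every covered person-year also generates Poisson
#' background (non-disease) contacts. Each disease-related contact receives a
#' disease diagnosis code with probability `coding_sensitivity` (otherwise a
#' background code), with codes drawn in the ICD version and digit precision
#' of the era in force for that setting and date. Disruption events multiply
#' the targeted parameter in their years.
#'
#' @param population a `registry`.
#' @param truth a `ground_truth` from [simulate_onsets()].
#' @param schedule an `era_schedule`; defaults to [default_era_schedule()].
#' @param config the [sim_config()].
#' @return data.frame of claims: person_id, service_date, setting, code,
#'   icd_version, sorted by person, date, setting (hospital first).
#' @export
simulate_claims <- function(population, truth, schedule = NULL, config) {
  validate_sim_config(config)
  if (is.null(schedule)) schedule <- default_era_schedule(config$span)
  grid <- truth$grid
  with_stream(config$seed, "claims", {
    case_years <- grid[!is.na(onset_year) & year >= onset_year]
    case_years[, is_onset_year := year == onset_year]

    vr <- effective_param(config, "visit_rate", case_years$year)
    hr <- effective_param(config, "hosp_rate", case_years$year)

    # physician contacts: diagnostic contact on the onset date, plus Poisson
    # follow-ups uniform over the remainder of the year
    n_phys <- rpois(nrow(case_years), vr)
    phys_start <- as.numeric(data.table::fifelse(
      case_years$is_onset_year, case_years$onset_date, year_start(case_years$year)
    ))
    phys_end <- as.numeric(year_end(case_years$year))
    phys <- data.table::data.table(
      person_id = rep(case_years$person_id, n_phys),
      date = as.Date(
        floor(runif(sum(n_phys), rep(phys_start, n_phys), rep(phys_end, n_phys) + 1)),
        origin = "1970-01-01"
      ),
      year = rep(case_years$year, n_phys),
      setting = "physician", disease = TRUE
    )
    diag_contact <- case_years[is_onset_year == TRUE, .(
      person_id,
      date = onset_date, year, setting = "physician", disease = TRUE
    )]

    n_hosp <- rpois(nrow(case_years), hr)
    hosp <- data.table::data.table(
      person_id = rep(case_years$person_id, n_hosp),
      date = as.Date(
        floor(runif(sum(n_hosp), rep(phys_start, n_hosp), rep(phys_end, n_hosp) + 1)),
        origin = "1970-01-01"
      ),
      year = rep(case_years$year, n_hosp),
      setting = "hospital", disease = TRUE
    )

    disease_contacts <- data.table::rbindlist(list(diag_contact, phys, hosp), use.names = TRUE)
    cs <- effective_param(config, "coding_sensitivity", disease_contacts$year)
    disease_contacts[, coded := runif(.N) < cs]

    # background contacts for every covered person-year
    n_bg <- rpois(nrow(grid), config$background_rate)
    n_bgh <- rpois(nrow(grid), config$background_hosp_rate)
    bg <- data.table::data.table(
      person_id = c(rep(grid$person_id, n_bg), rep(grid$person_id, n_bgh)),
      date = as.Date(
        floor(runif(
          sum(n_bg) + sum(n_bgh),
          as.numeric(year_start(c(rep(grid$year, n_bg), rep(grid$year, n_bgh)))),
          as.numeric(year_end(c(rep(grid$year, n_bg), rep(grid$year, n_bgh)))) + 1
        )),
        origin = "1970-01-01"
      ),
      setting = c(rep("physician", sum(n_bg)), rep("hospital", sum(n_bgh))),
      disease = FALSE, coded = FALSE
    )

    contacts <- data.table::rbindlist(list(
      disease_contacts[, .(person_id, date, setting, disease, coded)], bg
    ), use.names = TRUE)

    era <- era_lookup(schedule, contacts$setting, contacts$date)
    contacts[, icd_version := era$icd_version]
    contacts[, code := character(.N)]
    dz <- which(contacts$disease & contacts$coded)
    if (length(dz)) {
      contacts$code[dz] <- random_diabetes_code(
        length(dz), contacts$icd_version[dz], era$digit_precision[dz]
      )
    }
    other <- which(!(contacts$disease & contacts$coded))
    if (length(other)) {
      contacts$code[other] <- random_background_code(length(other), contacts$icd_version[other])
    }
    claims <- contacts[, .(person_id, service_date = date, setting, code, icd_version)]
    data.table::setorder(claims, person_id, service_date, setting)
    as.data.frame(claims)
  })
}

#' Simulate a complete study dataset
#'
#' Runs [generate_population()], [simulate_onsets()] and [simulate_claims()]
#' under one configuration and era schedule.
#'
#' @inheritParams simulate_claims
#' @param config a [sim_config()].
#' @return list with `registry`, `truth`, `claims`, `config`, `schedule`.
#' @export
simulate_study <- function(config, schedule = NULL) {
  if (is.null(schedule)) schedule <- default_era_schedule(config$span)
  registry <- generate_population(config)
  truth <- simulate_onsets(registry, config)
  claims <- simulate_claims(registry, truth, schedule, config)
  structure(
    list(
      registry = registry, truth = truth, claims = claims,
      config = config, schedule = schedule
    ),
    class = "sim_study"
  )
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `registry.csv` (one row per coverage spell), `claims.csv`, and
#' `truth.csv` (ground-truth incident and prevalent counts keyed by year,
#' age group and sex), all with ISO-8601 dates.
#'
#' @param study a `sim_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_study_data <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- merge(study$registry$persons, study$registry$spells, by = "person_id")
  reg <- reg[order(reg$person_id, reg$spell_start), ]
  paths <- file.path(dir, c("registry.csv", "claims.csv", "truth.csv"))
  write.csv(reg, paths[1], row.names = FALSE)
  write.csv(study$claims, paths[2], row.names = FALSE)
  tr <- merge(study$truth$incident, study$truth$prevalent,
    by = c("year", "age_group", "sex"), suffixes = c("_incident", "_prevalent")
  )
  write.csv(tr, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a registry written by [write_study_data()]
#' @param path path to `registry.csv`.
#' @return a `registry` object.
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$birth_date <- as.Date(df$birth_date)
  df$spell_start <- as.Date(df$spell_start)
  df$spell_end <- as.Date(df$spell_end)
  persons <- unique(df[, c("person_id", "sex", "birth_date")])
  rownames(persons) <- NULL
  spells <- df[, c("person_id", "spell_start", "spell_end")]
  structure(list(persons = persons, spells = spells), class = "registry")
}

#' Read a claims table written by [write_study_data()]
#' @param path path to `claims.csv`.
#' @return data.frame of claims with Date service dates.
#' @export
read_claims <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$service_date <- as.Date(df$service_date)
  df
}
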