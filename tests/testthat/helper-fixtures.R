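# A hand-built 20-person fixture exercising the case-definition edge cases:
# spacing-rule boundaries (29/30 days), window boundaries (364/365 days),
# lookback boundaries (exactly 1095 days), hospital/physician branches,
# tie dates, decoy codes and out-of-coverage claims.
fixture_study <- function() {
  person <- function(id, birth) {
    data.frame(person_id = id, sex = if (as.integer(substr(id, 2, 3)) %% 2) "F" else "M",
      birth_date = as.Date(birth))
  }
  # broad coverage: birth to 18th birthday
  persons <- rbind(
    person("p01", "1982-06-15"), person("p02", "1984-01-20"),
    person("p03", "1987-09-02"), person("p04", "1992-03-11"),
    person("p05", "1993-07-19"), person("p06", "1980-11-05"),
    person("p07", "1980-04-28"), person("p08", "1981-02-14"),
    person("p09", "1980-08-30"), person("p10", "1990-12-01"),
    person("p11", "1985-05-05"), person("p12", "1986-10-17"),
    person("p13", "1983-04-09"), person("p14", "1997-01-23"),
    person("p15", "1995-06-07"), person("p16", "2002-02-28"),
    person("p17", "1968-03-03"), person("p18", "2001-09-12"),
    person("p19", "1994-04-01"), person("p20", "1983-12-25")
  )
  spells <- data.frame(
    person_id = persons$person_id,
    spell_start = persons$birth_date,
    spell_end = persons$birth_date + round(18 * 365.25) - 1
  )
  # p13's coverage ends 1995-12-31 (claims after are out of coverage)
  spells$spell_end[spells$person_id == "p13"] <- as.Date("1995-12-31")
  registry <- structure(list(persons = persons, spells = spells), class = "registry")

  cl <- function(id, date, setting = "physician", code = "250", icd = "ICD9CM") {
    data.frame(person_id = id, service_date = as.Date(date), setting = setting,
      code = code, icd_version = icd)
  }
  claims <- rbind(
    # p01: two physician claims 75 days apart (worked spec example)
    cl("p01", "1990-03-01"), cl("p01", "1990-05-15"),
    # p02: a single hospital separation
    cl("p02", "1992-06-10", "hospital", "25001"),
    # p03: two physician visits 10 days apart (fails the 30-day rule)
    cl("p03", "1995-04-01"), cl("p03", "1995-04-11"),
    # p04: exactly 30 days apart (boundary satisfied)
    cl("p04", "2000-01-01"), cl("p04", "2000-01-31"),
    # p05: 29 days apart (boundary violated)
    cl("p05", "2001-01-01"), cl("p05", "2001-01-30"),
    # p06: 364 days apart (inside the 1-year window)
    cl("p06", "1988-01-10"), cl("p06", "1989-01-08"),
    # p07: 365 days apart (outside 1-year, inside 2-year window)
    cl("p07", "1988-01-10"), cl("p07", "1989-01-09"),
    # p08: isolated claim, then a qualifying pair > 3 years later (incident)
    cl("p08", "1985-02-01"), cl("p08", "1989-06-01"), cl("p08", "1989-07-15"),
    # p09: isolated claim inside the lookback of the later pair (prevalent)
    cl("p09", "1987-01-01"), cl("p09", "1989-06-01"), cl("p09", "1989-07-15"),
    # p10: hospital and physician on the same date
    cl("p10", "1998-05-05", "hospital", "25002"), cl("p10", "1998-05-05"),
    # p11: no claims at all -> omitted entirely
    # p12: only non-disease codes
    cl("p12", "1994-02-02", code = "465"), cl("p12", "1994-03-02", code = "558"),
    # p13: disease claims dated after coverage ended
    cl("p13", "1997-06-01"), cl("p13", "1997-08-01"),
    # p14: five well-spaced physician visits in five months
    cl("p14", "2005-01-10"), cl("p14", "2005-02-15"), cl("p14", "2005-03-20"),
    cl("p14", "2005-04-25"), cl("p14", "2005-05-30"),
    # p15: five visits 20 days apart (greedy spaced count = 3)
    cl("p15", "2003-03-01"), cl("p15", "2003-03-21"), cl("p15", "2003-04-10"),
    cl("p15", "2003-04-30"), cl("p15", "2003-05-20"),
    # p16: lone physician visit, hospital separation 15 months later
    cl("p16", "2010-03-01"), cl("p16", "2011-06-01", "hospital", "E10.1", "ICD10CA"),
    # p17: ICDA-8 era codes (249x hospital, 250 physician)
    cl("p17", "1976-05-12", code = "250", icd = "ICDA8"),
    cl("p17", "1976-07-04", "hospital", "2493", "ICDA8"),
    # p18: ICD-10-CA era hospital codes
    cl("p18", "2010-10-01", "hospital", "E13.9", "ICD10CA"),
    # p19: eight visits roughly 80 days apart spanning two years
    cl("p19", "2006-01-05"), cl("p19", "2006-03-26"), cl("p19", "2006-06-14"),
    cl("p19", "2006-09-02"), cl("p19", "2006-11-21"), cl("p19", "2007-02-09"),
    cl("p19", "2007-04-30"), cl("p19", "2007-07-19"),
    # p20: prior claim exactly 1095 days before the qualifying pair
    cl("p20", "1993-06-02"), cl("p20", "1996-06-01"), cl("p20", "1996-07-10"),
    # decoy background codes sprinkled on several persons
    cl("p01", "1989-11-20", code = "465"), cl("p08", "1988-12-01", code = "813"),
    cl("p14", "2004-06-30", code = "382")
  )
  claims <- claims[order(claims$person_id, claims$service_date), ]
  rownames(claims) <- NULL
  list(registry = registry, claims = claims)
}

# A fast, small simulation configuration for pipeline unit tests: fewer
# persons with a higher hazard so cells clear the suppression rule quickly.
fast_sim_config <- function(seed = 1L, ...) {
  sim_config(
    n_persons = 25000L, span = c(1965L, 2016L),
    incidence_hazard = function(year) {
      0.006 + 0.004 * pmin(pmax((year - 1975) / 41, 0), 1)
    },
    seed = seed, ...
  )
}
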