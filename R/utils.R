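#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats AIC coef logLik model.matrix offset p.adjust pchisq
#'   pnorm predict quantile rbinom rnorm rpois runif sd setNames vcov
#'   complete.cases
#' @importFrom utils write.csv
NULL

# data.table NSE columns
utils::globalVariables(c(
  ".", ".I", ".N", "age", "birth_date", "case_count", "case_date",
  "cohort_size", "code", "count", "covered", "crude_rate", "cases",
  "expected", "group", "i.row_id", "icd_version", "incident", "is_onset_year",
  "lower", "observed", "onset_date", "onset_year", "ooc", "person_id",
  "row_id", "sd_pooled", "service_date", "setting", "setting_rank",
  "sex", "spell_end", "spell_start", "upper", "year"
))

# Deterministic sub-stream seed: polynomial hash of the stream name folded
# into the master seed, kept below 2^31 so set.seed() accepts it.
stream_seed <- function(master_seed, stream) {
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 31 + b) %% 2147483647L
  as.integer((as.numeric(master_seed) * 7919 + h) %% 2147483647)
}

# Evaluate a block with its own RNG stream, restoring the caller's RNG state.
with_stream <- function(master_seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(master_seed, stream))
  force(expr)
}

year_start <- function(y) as.Date(sprintf("%d-01-01", y))
year_end <- function(y) as.Date(sprintf("%d-12-31", y))
mid_year <- function(y) as.Date(sprintf("%d-07-01", y))

# Age in completed years at date `at` for someone born on `birth`.
age_at <- function(birth, at) {
  ab <- as.POSIXlt(birth)
  aa <- as.POSIXlt(at)
  age <- aa$year - ab$year
  before_birthday <- (aa$mon < ab$mon) | (aa$mon == ab$mon & aa$mday < ab$mday)
  age - as.integer(before_birthday)
}

# Age attained on July 1 of `year`, vectorised without POSIXlt.
age_at_midyear <- function(birth, year) {
  by <- data.table::year(birth)
  bm <- data.table::month(birth)
  bd <- data.table::mday(birth)
  year - by - as.integer(bm > 7L | (bm == 7L & bd > 1L))
}

# first and last calendar years a spell covers in full
full_year_bounds <- function(spells) {
  sy <- data.table::year(spells$spell_start)
  ey <- data.table::year(spells$spell_end)
  list(
    y0 = sy + as.integer(spells$spell_start > year_start(sy)),
    y1 = ey - as.integer(spells$spell_end < year_end(ey))
  )
}

# years covered in full by each spell, as a long table (person_id, year)
expand_years <- function(person_id, y0, y1) {
  keep <- y1 >= y0
  reps <- (y1 - y0 + 1L)[keep]
  data.table::data.table(
    person_id = rep(person_id[keep], reps),
    year = rep(y0[keep], reps) + sequence(reps) - 1L
  )
}

#' Age groups used for stratified surveillance counts
#'
#' Counts are aggregated into two paediatric age groups, `0-9` and `10-17`
#' completed years, by age attained on July 1 of the counting year.
#'
#' @param age integer vector of ages in completed years.
#' @return factor with levels `"0-9"` and `"10-17"`; ages outside 0--17 are `NA`.
#' @export
age_group <- function(age) {
  g <- ifelse(age >= 0 & age <= 9, "0-9",
    ifelse(age >= 10 & age <= 17, "10-17", NA_character_)
  )
  factor(g, levels = c("0-9", "10-17"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
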