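#' Parse a case-definition algorithm name
#'
#' Case-definition algorithms are named on the pattern `"K: a + H or b + P"`
#' (hospital/physician combination) or `"K: b + P"` (physician only), read as
#' "at least `a` hospital separations or at least `b` physician visits within
#' `K` years". For physician-only definitions requiring two or more visits,
#' qualifying visits must additionally be at least 30 days apart.
#'
#' @param name algorithm name, e.g. `"2: 1 + H or 2 + P"` or `"1: 2 + P"`.
#' @return an `algorithm_spec`: list with `name`, `window_years`,
#'   `min_hospital` (0 when hospital records are not used), `min_physician`,
#'   and `min_days_apart` (30 when the spacing rule applies, else 0).
#' @examples
#' parse_algorithm_name("2: 1 + H or 2 + P")
#' parse_algorithm_name("2: 5 + P")
#' @export
parse_algorithm_name <- function(name) {
  grammar <- "K: [a + H or ] b + P  (K in 1..3, a = 1, b in 1..5)"
  m <- regmatches(
    name,
    regexec("^\\s*([123])\\s*:\\s*(?:([0-9]+)\\s*\\+\\s*H\\s+or\\s+)?([1-5])\\s*\\+\\s*P\\s*$",
      name,
      ignore.case = TRUE
    )
  )[[1]]
  if (length(m) == 0L) {
    stop("malformed algorithm name ", sQuote(name), "; expected grammar: ", grammar)
  }
  window_years <- as.integer(m[2])
  min_hospital <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  min_physician <- as.integer(m[4])
  if (min_hospital > 1L) {
    stop("malformed algorithm name ", sQuote(name), "; expected grammar: ", grammar)
  }
  physician_only <- min_hospital == 0L
  spec <- list(
    name = name,
    window_years = window_years,
    min_hospital = min_hospital,
    min_physician = min_physician,
    min_days_apart = if (physician_only && min_physician >= 2L) 30L else 0L
  )
  class(spec) <- "algorithm_spec"
  spec
}

#' @export
print.algorithm_spec <- function(x, ...) {
  cat(
    "<algorithm_spec>", x$name, "- window", x$window_years, "y;",
    if (x$min_hospital > 0) paste0(">=", x$min_hospital, " hospital or ") else "",
    ">=", x$min_physician, "physician",
    if (x$min_days_apart > 0) paste0("(>=", x$min_days_apart, " days apart)") else "", "\n"
  )
  invisible(x)
}

#' The 18 validated juvenile diabetes case-definition algorithms
#'
#' Eight hospital/physician combination definitions (windows 1--3 years) and
#' ten physician-only definitions (1--5 visits in 1 or 2 years).
#'
#' @return character vector of 18 algorithm names parseable by
#'   [parse_algorithm_name()].
#' @export
juvenile_diabetes_algorithms <- function() {
  c(
    "1: 1 + H or 1 + P", "1: 1 + H or 2 + P", "1: 1 + H or 3 + P",
    "1: 1 + H or 4 + P", "2: 1 + H or 1 + P", "2: 1 + H or 2 + P",
    "3: 1 + H or 1 + P", "3: 1 + H or 2 + P",
    "1: 1 + P", "1: 2 + P", "1: 3 + P", "1: 4 + P", "1: 5 + P",
    "2: 1 + P", "2: 2 + P", "2: 3 + P", "2: 4 + P", "2: 5 + P"
  )
}

#' Test whether a diagnosis code denotes the disease of interest
#'
#' Prefix matching against the juvenile diabetes code sets: ICDA-8 codes
#' beginning 249 or 250; ICD-9-CM codes beginning 250; ICD-10-CA codes
#' beginning E10 through E14. The comparison ignores dots and is
#' case-insensitive on the leading letter.
#'
#' @param code character vector of diagnosis codes.
#' @param icd_version character vector (recycled): `"ICDA8"`, `"ICD9CM"` or
#'   `"ICD10CA"`.
#' @return logical vector.
#' @examples
#' is_diabetes_code("2500", "ICD9CM")
#' is_diabetes_code("E11.9", "ICD10CA")
#' @export
is_diabetes_code <- function(code, icd_version) {
  n <- max(length(code), length(icd_version))
  code <- rep_len(code, n)
  icd_version <- rep_len(icd_version, n)
  if (any(!nzchar(code))) stop("diagnosis codes must be non-empty")
  bad <- !icd_version %in% c("ICDA8", "ICD9CM", "ICD10CA")
  if (any(bad)) stop("unknown ICD version: ", paste(unique(icd_version[bad]), collapse = ", "))
  norm <- toupper(gsub(".", "", code, fixed = TRUE))
  out <- logical(n)
  v <- icd_version == "ICDA8"
  out[v] <- startsWith(norm[v], "249") | startsWith(norm[v], "250")
  v <- icd_version == "ICD9CM"
  out[v] <- startsWith(norm[v], "250")
  v <- icd_version == "ICD10CA"
  out[v] <- substr(norm[v], 1, 3) %in% c("E10", "E11", "E12", "E13", "E14")
  out
}

#' Greedy selection of visits separated by a minimum gap
#'
#' Keeps the first date, then each later date at least `min_days_apart` days
#' after the last kept date. Earliest-first greedy selection returns a
#' maximum-cardinality subset under the spacing constraint.
#'
#' @param dates sorted ascending vector of Dates.
#' @param min_days_apart minimum gap in days; 0 returns the input unchanged.
#' @return the kept dates.
#' @export
select_spaced_visits <- function(dates, min_days_apart) {
  if (length(dates) <= 1L || min_days_apart <= 0) {
    return(dates)
  }
  if (is.unsorted(dates)) stop("dates must be sorted ascending")
  keep <- logical(length(dates))
  keep[1] <- TRUE
  last <- dates[1]
  for (i in seq_along(dates)[-1]) {
    if (as.numeric(dates[i] - last) >= min_days_apart) {
      keep[i] <- TRUE
      last <- dates[i]
    }
  }
  dates[keep]
}
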