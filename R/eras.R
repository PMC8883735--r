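#' ICD coding-era schedule
#'
#' Administrative claims switch ICD versions on fixed calendar dates that
#' differ by care setting. An era schedule maps each (setting, service date)
#' to the ICD version and digit precision in force. The default schedule
#' mirrors a Canadian provincial repository: hospital abstracts coded in
#' 4-digit ICDA-8 until 1979-03-31, 5-digit ICD-9-CM until 2004-03-31 and
#' 5-digit ICD-10-CA afterwards; physician claims coded in ICDA-8 until
#' 1979-03-31 and ICD-9-CM afterwards, at the 3-digit level until 2015-03-31
#' and 5 digits from 2015-04-01.
#'
#' @param spans `(first_year, last_year)` calendar span the schedule must cover.
#' @return an object of class `era_schedule`: a data.frame with columns
#'   `setting`, `start_date`, `icd_version`, `digit_precision`.
#' @export
default_era_schedule <- function(spans = c(1972L, 2018L)) {
  sched <- data.frame(
    setting = c("hospital", "hospital", "hospital", "physician", "physician", "physician"),
    start_date = as.Date(c(
      sprintf("%d-01-01", spans[1]), "1979-04-01", "2004-04-01",
      sprintf("%d-01-01", spans[1]), "1979-04-01", "2015-04-01"
    )),
    icd_version = c("ICDA8", "ICD9CM", "ICD10CA", "ICDA8", "ICD9CM", "ICD9CM"),
    digit_precision = c(4L, 5L, 5L, 3L, 3L, 5L),
    stringsAsFactors = FALSE
  )
  structure(sched, class = c("era_schedule", "data.frame"), span = as.integer(spans))
}

# Vectorised lookup: ICD version and digit precision for (setting, date).
era_lookup <- function(schedule, setting, dates) {
  stopifnot(inherits(schedule, "era_schedule"))
  n <- max(length(setting), length(dates))
  setting <- rep_len(setting, n)
  dates <- rep_len(dates, n)
  version <- character(n)
  digits <- integer(n)
  for (s in unique(setting)) {
    rows <- schedule[schedule$setting == s, , drop = FALSE]
    rows <- rows[order(rows$start_date), , drop = FALSE]
    sel <- setting == s
    idx <- findInterval(as.numeric(dates[sel]), as.numeric(rows$start_date))
    if (any(idx == 0)) stop("service date precedes the era schedule for setting ", s)
    version[sel] <- rows$icd_version[idx]
    digits[sel] <- rows$digit_precision[idx]
  }
  list(icd_version = version, digit_precision = digits)
}

# Draw diagnosis codes for the disease of interest (juvenile diabetes) in the
# era's ICD version, truncated/padded to the era's digit precision.
random_diabetes_code <- function(n, icd_version, digit_precision) {
  out <- character(n)
  for (v in unique(icd_version)) {
    sel <- icd_version == v
    m <- sum(sel)
    prec <- digit_precision[sel]
    if (v == "ICDA8") {
      base <- sample(c("249", "250"), m, replace = TRUE)
      out[sel] <- ifelse(prec >= 4,
        paste0(base, sample(0:9, m, replace = TRUE)), base
      )
    } else if (v == "ICD9CM") {
      extra <- ifelse(prec >= 5,
        sprintf("%d%d", sample(0:9, m, replace = TRUE), sample(0:3, m, replace = TRUE)),
        ""
      )
      out[sel] <- paste0("250", extra)
    } else if (v == "ICD10CA") {
      base <- sprintf("E1%d", sample(0:4, m, replace = TRUE))
      out[sel] <- paste0(base, ".", sample(0:9, m, replace = TRUE))
    } else {
      stop("unknown ICD version: ", v)
    }
  }
  out
}

# Background (non-disease) codes so that ascertainment must filter by code.
random_background_code <- function(n, icd_version) {
  out <- character(n)
  for (v in unique(icd_version)) {
    sel <- icd_version == v
    m <- sum(sel)
    out[sel] <- if (v == "ICD10CA") {
      sample(c("J06.9", "K52.9", "S52.5", "H66.9"), m, replace = TRUE)
    } else {
      # valid in both ICDA-8 and ICD-9-CM at 3 digits; never 249/250
      sample(c("465", "558", "813", "382"), m, replace = TRUE)
    }
  }
  out
}
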