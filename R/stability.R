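#' Study periods defined by ICD versions
#'
#' The study span 1975--2016 partitions into three ICD periods by the
#' version in force at the start of each year (ICDA-8 1975--1979, ICD-9
#' 1980--2004, ICD-9/10 2005--2016; the last period is truncated at 2016
#' because out-of-control classification stops there). Two 5-year
#' implementation periods bracket each version switch: the two years before,
#' the switch year, and the two years after.
#'
#' @return a `period_set`: list with `icd_periods` and
#'   `implementation_periods`, each a named list of year vectors.
#' @export
default_period_set <- function() {
  ps <- list(
    icd_periods = list(
      "ICDA-8 (1975-1979)" = 1975:1979,
      "ICD-9 (1980-2004)" = 1980:2004,
      "ICD-9/10 (2005-2016)" = 2005:2016
    ),
    implementation_periods = list(
      "ICDA-8 to -9 (1977-1981)" = 1977:1981,
      "ICD-9 to -9/10 (2002-2006)" = 2002:2006
    )
  )
  structure(ps, class = "period_set")
}

#' Proportion of out-of-control years
#'
#' @param series an `ooc_series` (or named logical vector).
#' @param years years to restrict to (default: all years in the series).
#' @return flagged-year count divided by the number of years.
#' @export
ooc_proportion <- function(series, years = NULL) {
  if (is.null(years)) years <- as.integer(names(series))
  if (length(years) == 0L) stop("empty year range")
  sel <- series[as.character(years)]
  if (anyNA(sel)) stop("years outside the series coverage")
  mean(sel)
}

#' McNemar test on paired out-of-control classifications
#'
#' Compares two algorithms' yearly out-of-control flags over the same years.
#' With discordant counts `b` (reference flagged, comparison not) and `c`
#' (the converse): when `b + c < 10` the exact two-sided binomial test is
#' used, `p = min(1, 2 * P(X <= min(b, c)))` for `X ~ Binomial(b + c, 1/2)`;
#' otherwise the continuity-corrected chi-squared statistic
#' `(|b - c| - 1)^2 / (b + c)` on 1 degree of freedom. Identical series
#' (`b + c = 0`) give `p = 1` with `identical = TRUE` so reports can render
#' them as NA.
#'
#' @param ref,other `ooc_series` objects for the same outcome and k.
#' @param years years to compare over.
#' @return a one-row data.frame: b, c, method, statistic, p_value, identical.
#' @export
mcnemar_ooc <- function(ref, other, years = NULL) {
  if (is.null(years)) years <- as.integer(names(ref))
  a_out <- attr(ref, "outcome")
  b_out <- attr(other, "outcome")
  if (!is.null(a_out) && !is.null(b_out) &&
    (!identical(a_out, b_out) || !identical(attr(ref, "k"), attr(other, "k")))) {
    stop("series must share outcome and control-limit multiplier")
  }
  r <- ref[as.character(years)]
  o <- other[as.character(years)]
  if (anyNA(r) || anyNA(o)) stop("series do not cover the requested years")
  b <- sum(r & !o)
  cc <- sum(!r & o)
  n <- b + cc
  if (n == 0L) {
    return(data.frame(
      b = 0L, c = 0L, method = "exact", statistic = NA_real_,
      p_value = 1, identical = TRUE
    ))
  }
  if (n < 10L) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
    data.frame(
      b = b, c = cc, method = "exact", statistic = NA_real_,
      p_value = p, identical = FALSE
    )
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    data.frame(
      b = b, c = cc, method = "approximate", statistic = stat,
      p_value = pchisq(stat, df = 1, lower.tail = FALSE), identical = FALSE
    )
  }
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down familywise-error adjustment: with the p-values sorted
#' ascending, the i-th adjusted value is the running maximum of
#' `min(1, (m - j + 1) * p_(j))` over `j <= i`, returned in input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
holm_bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "holm")
}

#' Agreement-by-year across algorithms
#'
#' For each year, the fraction of algorithms whose control chart flags it as
#' out-of-control.
#'
#' @param all_series list of `ooc_series` over common years.
#' @return named numeric vector (names are years), values in `[0, 1]`.
#' @export
agreement_by_year <- function(all_series) {
  stopifnot(length(all_series) >= 1L)
  yrs <- names(all_series[[1]])
  mat <- vapply(all_series, function(s) {
    v <- s[yrs]
    if (anyNA(v)) stop("series do not share common years")
    as.numeric(v)
  }, numeric(length(yrs)))
  setNames(rowMeans(matrix(mat, nrow = length(yrs))), yrs)
}

#' Crude rates and period summaries
#'
#' The annual crude rate is total cases divided by total covered persons,
#' per 100,000. For each ICD period, reports the average of the annual
#' rates and the average annual rate of change (last-year rate minus
#' first-year rate, divided by the number of years in the period).
#'
#' @param counts a `count_table`.
#' @param periods a `period_set`.
#' @return list with `annual` (data.frame year, cases, covered, crude_rate)
#'   and `periods` (data.frame period, average_rate, average_annual_change).
#' @export
rate_summary <- function(counts, periods = default_period_set()) {
  dt <- data.table::as.data.table(as.data.frame(counts))
  annual <- dt[, .(cases = sum(case_count), covered = sum(cohort_size)), by = year]
  data.table::setorder(annual, year)
  if (any(annual$covered <= 0)) stop("zero covered population in some year")
  annual[, crude_rate := cases / covered * 1e5]
  per <- lapply(names(periods$icd_periods), function(nm) {
    yrs <- periods$icd_periods[[nm]]
    sub <- annual[year %in% yrs]
    if (nrow(sub) == 0L) stop("counts do not cover period ", nm)
    data.frame(
      period = nm,
      average_rate = mean(sub$crude_rate),
      average_annual_change =
        (sub$crude_rate[nrow(sub)] - sub$crude_rate[1]) / nrow(sub)
    )
  })
  list(annual = as.data.frame(annual), periods = do.call(rbind, per))
}

#' Compare all algorithms to a reference across period families
#'
#' Runs [mcnemar_ooc()] for every comparison algorithm against the reference
#' within each family of years (the whole study span, each ICD period, each
#' implementation period), then applies the Holm-Bonferroni adjustment
#' separately within each family.
#'
#' @param reference the reference `ooc_series`.
#' @param others named list of comparison `ooc_series`.
#' @param periods a `period_set`.
#' @return data.frame with one row per algorithm x family: family,
#'   algorithm, b, c, method, p_value, p_adjusted, identical.
#' @export
compare_all <- function(reference, others, periods = default_period_set()) {
  stopifnot(length(others) >= 1L)
  all_years <- as.integer(names(reference))
  families <- c(
    list("All years" = all_years),
    periods$icd_periods, periods$implementation_periods
  )
  out <- list()
  for (fam in names(families)) {
    yrs <- families[[fam]]
    rows <- lapply(names(others), function(alg) {
      r <- mcnemar_ooc(reference, others[[alg]], yrs)
      cbind(data.frame(family = fam, algorithm = alg), r)
    })
    fam_df <- do.call(rbind, rows)
    fam_df$p_adjusted <- holm_bonferroni(fam_df$p_value)
    out[[fam]] <- fam_df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
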