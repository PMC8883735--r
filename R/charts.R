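#' Aggregate stratum predictions to a yearly chart point
#'
#' Expected count for a year is the sum of model-predicted stratum means;
#' the pooled SD is the standard deviation of a sum of independent stratum
#' counts, i.e. the square root of the summed per-stratum outcome variances;
#' the observed total sums the (possibly imputed) observed cells.
#'
#' @param mu per-stratum predicted means for one year.
#' @param v per-stratum outcome variances.
#' @param observed per-stratum observed counts.
#' @return list with `expected`, `sd_pooled`, `observed`.
#' @export
aggregate_year <- function(mu, v, observed) {
  if (length(mu) < 4L) {
    warning("aggregating over ", length(mu), " strata (expected 4)", call. = FALSE)
  }
  list(expected = sum(mu), sd_pooled = sqrt(sum(v)), observed = sum(observed))
}

#' Flag an observation as out-of-control
#'
#' An observation is out-of-control when it lies strictly outside the
#' control limits `expected +/- k * sd_pooled`; observations exactly on a
#' limit are in-control.
#'
#' @param observed,expected,sd_pooled chart quantities (vectors recycle).
#' @param k control-limit multiplier.
#' @return logical vector.
#' @export
flag_year <- function(observed, expected, sd_pooled, k = 0.8) {
  stopifnot(all(sd_pooled > 0))
  observed < expected - k * sd_pooled | observed > expected + k * sd_pooled
}

#' Build an observed-expected control chart
#'
#' One chart point per study year: observed yearly totals against
#' model-expected totals with control limits at `expected +/- k * pooled SD`,
#' and an out-of-control flag for points strictly outside the limits.
#'
#' @param fit a `trend_fit`.
#' @param k control-limit multiplier (0.8 default; 2 for the relaxed
#'   sensitivity setting).
#' @param sd_type `"outcome"` pools the model outcome variances (NB:
#'   `mu + mu^2/theta`; quasi-Poisson: `phi * mu`); `"prediction"` instead
#'   pools squared standard errors of the predicted means (delta method), a
#'   narrower prediction-uncertainty variant for comparison.
#' @return a `control_chart`: data.frame (year, observed, expected,
#'   sd_pooled, lower, upper, ooc) with attributes `algorithm`, `outcome`, `k`.
#' @export
build_chart <- function(fit, k = 0.8, sd_type = c("outcome", "prediction")) {
  stopifnot(inherits(fit, "trend_fit"))
  sd_type <- match.arg(sd_type)
  preds <- fit$predictions
  if (sd_type == "prediction") preds$v <- prediction_variance(fit)
  dt <- data.table::as.data.table(preds)
  yearly <- dt[, .(
    observed = sum(observed), expected = sum(mu), sd_pooled = sqrt(sum(v))
  ), by = year]
  data.table::setorder(yearly, year)
  yearly[, `:=`(
    lower = expected - k * sd_pooled,
    upper = expected + k * sd_pooled
  )]
  yearly[, ooc := flag_year(observed, expected, sd_pooled, k)]
  out <- as.data.frame(yearly)
  structure(out,
    class = c("control_chart", "data.frame"),
    algorithm = fit$algorithm, outcome = fit$outcome, k = k, sd_type = sd_type
  )
}

# Delta-method variance of the predicted mean for every cell.
prediction_variance <- function(fit) {
  preds <- fit$predictions
  df <- preds
  df$age_group <- factor(df$age_group, levels = c("0-9", "10-17"))
  df$sex <- factor(df$sex, levels = c("F", "M"))
  if (is.null(fit$knots)) {
    df$year1 <- df$year
    cols <- "year1"
  } else {
    b <- rcs_eval(df$year, fit$knots)
    for (j in seq_len(ncol(b))) df[[colnames(b)[j]]] <- b[, j]
    cols <- colnames(b)
  }
  X <- model.matrix(
    stats::as.formula(paste("~ age_group + sex +", paste(cols, collapse = " + "))),
    data = df
  )
  X <- X[, names(fit$coefficients), drop = FALSE]
  se_eta2 <- rowSums((X %*% fit$vcov) * X)
  preds$mu^2 * se_eta2
}

#' @export
print.control_chart <- function(x, ...) {
  cat(
    "<control_chart>", attr(x, "outcome"), "for", attr(x, "algorithm"),
    "- k =", attr(x, "k"), ";", sum(x$ooc), "of", nrow(x), "years out-of-control\n"
  )
  invisible(x)
}

#' Plot an observed-expected control chart
#'
#' Observed yearly counts against the model-expected line with shaded
#' control limits; out-of-control years are highlighted and vertical rules
#' mark ICD-version change years.
#'
#' @param x a `control_chart`.
#' @param icd_change_years years to mark with vertical rules.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot.control_chart <- function(x, icd_change_years = c(1979, 2004), ...) {
  df <- as.data.frame(x)
  ggplot2::ggplot(df, ggplot2::aes(x = year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
      fill = "grey85"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = expected), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = observed, colour = ooc), size = 1.6) +
    ggplot2::geom_vline(
      xintercept = icd_change_years, linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "black", `TRUE` = "red"), name = "out-of-control"
    ) +
    ggplot2::labs(
      title = paste0(
        attr(x, "outcome"), " — ", attr(x, "algorithm"),
        " (k = ", attr(x, "k"), ")"
      ),
      x = "year", y = "annual case count"
    ) +
    ggplot2::theme_minimal()
}

#' Extract the out-of-control series from a chart
#'
#' @param chart a `control_chart`.
#' @return an `ooc_series`: named logical vector (names are years) with
#'   attributes `algorithm`, `outcome`, `k`.
#' @export
ooc_series <- function(chart) {
  stopifnot(inherits(chart, "control_chart"))
  structure(setNames(chart$ooc, chart$year),
    class = "ooc_series",
    algorithm = attr(chart, "algorithm"), outcome = attr(chart, "outcome"),
    k = attr(chart, "k")
  )
}
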