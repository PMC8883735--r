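#' @rdname fit_incidence
#' @export
year_shapes <- function() c("linear", "rcs3", "rcs4", "rcs5")

# Build the modelling frame: covariates, year terms (linear or restricted
# cubic spline) and offset. Returns the augmented data plus bookkeeping on
# which columns carry the nonlinear part of the year effect.
trend_frame <- function(table, year_shape) {
  stopifnot(inherits(table, "count_table"))
  year_shape <- match.arg(year_shape, year_shapes())
  if (any(table$cohort_size <= 0)) {
    stop("all cells must have positive cohort_size (offset is log cohort size)")
  }
  df <- as.data.frame(table)
  df$age_group <- factor(df$age_group, levels = c("0-9", "10-17"))
  df$sex <- factor(df$sex, levels = c("F", "M"))
  if (year_shape == "linear") {
    df$year1 <- df$year
    year_cols <- "year1"
    knots <- NULL
  } else {
    n_knots <- as.integer(sub("rcs", "", year_shape))
    b <- rcs_basis(df$year, n_knots)
    knots <- b$knots
    for (j in seq_len(ncol(b$basis))) df[[colnames(b$basis)[j]]] <- b$basis[, j]
    year_cols <- colnames(b$basis)
  }
  list(
    data = df, year_cols = year_cols, nonlinear_cols = setdiff(year_cols, "year1"),
    knots = knots, year_shape = year_shape
  )
}

new_trend_fit <- function(outcome, frame, coefficients, vcov, dispersion, ic,
                          fit_stats, mu, v, model, algorithm) {
  preds <- frame$data[, c("year", "age_group", "sex", "case_count")]
  names(preds)[names(preds) == "case_count"] <- "observed"
  preds$mu <- mu
  preds$v <- v
  structure(
    list(
      outcome = outcome, year_shape = frame$year_shape, algorithm = algorithm,
      coefficients = coefficients, vcov = vcov, dispersion = dispersion,
      ic = ic, fit_stats = fit_stats, knots = frame$knots,
      nonlinear_cols = frame$nonlinear_cols, predictions = preds, model = model
    ),
    class = "trend_fit"
  )
}

#' Fit trend models to stratum count tables
#'
#' `fit_incidence()` fits a negative binomial log-link regression (counts
#' treated as independent across years) with age group, sex and year terms
#' and the log cohort size as offset; the shape parameter theta is estimated
#' by maximum likelihood and counted as a parameter in the AIC. Per-cell
#' outcome variance is `mu + mu^2 / theta`.
#'
#' `fit_prevalence()` fits a population-averaged Poisson log-link model by
#' estimating equations with AR(1) working correlation within age-sex series
#' (prevalent counts in successive years are serially correlated), robust
#' covariance, and moment-estimated scale phi; per-cell outcome variance is
#' `phi * mu`. Model adequacy is summarized by the marginal R-squared
#' (squared-error proportion of variance explained across all cells).
#'
#' @param table a `count_table` (after suppression handling).
#' @param year_shape one of `"linear"`, `"rcs3"`, `"rcs4"`, `"rcs5"`.
#' @return a `trend_fit` with coefficients, covariance, dispersion/scale,
#'   information criterion, fit statistics and per-cell predictions.
#' @export
fit_incidence <- function(table, year_shape = "linear") {
  frame <- trend_frame(table, year_shape)
  fml <- stats::as.formula(paste(
    "case_count ~ age_group + sex +",
    paste(frame$year_cols, collapse = " + "),
    "+ offset(log(cohort_size))"
  ))
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(fml, data = frame$data, control = stats::glm.control(maxit = 100)),
      warning = function(w) {
        # near-Poisson data drives theta towards infinity; theta.ml then
        # emits NaN/truncation warnings before the fit settles or errors
        # (the error path falls back to the Poisson limit below)
        if (grepl("limit reached|theta|NaNs produced|truncated", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$theta)) {
    # equidispersed counts: theta estimation diverges, so fit at the Poisson
    # limit with a fixed very large shape; AIC still counts theta
    theta <- 1e6
    fit <- stats::glm(fml, data = frame$data, family = MASS::negative.binomial(theta))
    aic <- AIC(fit) + 2
  } else {
    theta <- fit$theta
    aic <- AIC(fit)
  }
  mu <- as.numeric(predict(fit, type = "response"))
  v <- mu + mu^2 / theta
  resid_dof <- stats::df.residual(fit)
  new_trend_fit(
    outcome = "incidence", frame = frame,
    coefficients = coef(fit), vcov = vcov(fit), dispersion = theta,
    ic = aic,
    fit_stats = list(
      residual_deviance = fit$deviance, residual_dof = resid_dof,
      deviance_ratio = fit$deviance / resid_dof, logLik = as.numeric(logLik(fit))
    ),
    mu = mu, v = v, model = fit, algorithm = attr(table, "algorithm")
  )
}

#' @rdname fit_incidence
#' @export
fit_prevalence <- function(table, year_shape = "linear") {
  frame <- trend_frame(table, year_shape)
  df <- frame$data
  df$cluster <- interaction(df$age_group, df$sex, drop = TRUE)
  ord <- order(df$cluster, df$year)
  df <- df[ord, ]
  X <- model.matrix(
    stats::as.formula(paste("~ age_group + sex +", paste(frame$year_cols, collapse = " + "))),
    data = df
  )
  fit <- gee_ar1_poisson(
    y = df$case_count, X = X, offset = log(df$cohort_size), id = df$cluster
  )
  r2 <- 1 - sum((df$case_count - fit$fitted)^2) /
    sum((df$case_count - mean(df$case_count))^2)
  mu <- fit$fitted
  v <- fit$phi * mu
  # restore original cell order for predictions
  frame_ord <- frame
  frame_ord$data <- df
  new_trend_fit(
    outcome = "prevalence", frame = frame_ord,
    coefficients = fit$coefficients, vcov = fit$vcov_robust,
    dispersion = fit$phi, ic = qic(fit),
    fit_stats = list(marginal_r2 = r2, alpha = fit$alpha, iterations = fit$iterations),
    mu = mu, v = v, model = fit, algorithm = attr(table, "algorithm")
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(
    "<trend_fit>", x$outcome, "~", x$year_shape,
    if (!is.null(x$algorithm)) paste0("[", x$algorithm, "]") else "",
    "- IC", round(x$ic, 1), "\n"
  )
  invisible(x)
}

#' Select the shape of the year effect
#'
#' Fits the linear-year model and restricted cubic splines with 3, 4 and 5
#' knots, picks the spline with the lowest information criterion (AIC for
#' incidence, QIC for prevalence), and adopts it only when its nonlinear
#' terms improve significantly on the linear model: a likelihood ratio test
#' for the negative binomial incidence models, a joint robust Wald test of
#' the nonlinear spline coefficients for prevalence. Otherwise the linear
#' model is adopted.
#'
#' @param table a `count_table`.
#' @param outcome `"incidence"` or `"prevalence"`.
#' @param level significance level for the spline-vs-linear test.
#' @return the adopted `trend_fit`, with a `selection` attribute recording
#'   the candidate ICs, the best spline, the test used and its p-value.
#' @export
select_year_shape <- function(table, outcome = c("incidence", "prevalence"),
                              level = 0.05) {
  outcome <- match.arg(outcome)
  fitter <- if (outcome == "incidence") fit_incidence else fit_prevalence
  fits <- list()
  warnings_log <- character(0)
  for (shape in year_shapes()) {
    fits[[shape]] <- tryCatch(fitter(table, shape), error = function(e) {
      warnings_log <<- c(warnings_log, paste0(shape, ": ", conditionMessage(e)))
      NULL
    })
  }
  if (is.null(fits$linear)) {
    stop("linear-year model failed to converge: ", paste(warnings_log, collapse = "; "))
  }
  spline_fits <- Filter(Negate(is.null), fits[c("rcs3", "rcs4", "rcs5")])
  if (length(warnings_log)) {
    warning("model selection proceeding over convergent subset: ",
      paste(warnings_log, collapse = "; "),
      call. = FALSE
    )
  }
  if (length(spline_fits) == 0L) {
    chosen <- fits$linear
    sel <- list(
      ic = c(linear = fits$linear$ic), best_spline = NA_character_,
      test = NA_character_, p_value = NA_real_, adopted = "linear",
      warnings = warnings_log
    )
    attr(chosen, "selection") <- sel
    return(chosen)
  }
  ics <- vapply(spline_fits, function(f) f$ic, numeric(1))
  best <- spline_fits[[which.min(ics)]]

  if (outcome == "incidence") {
    stat <- 2 * (best$fit_stats$logLik - fits$linear$fit_stats$logLik)
    dof <- length(best$nonlinear_cols)
    p <- pchisq(max(stat, 0), df = dof, lower.tail = FALSE)
    test <- "LRT"
  } else {
    bn <- best$coefficients[best$nonlinear_cols]
    Vn <- best$vcov[best$nonlinear_cols, best$nonlinear_cols, drop = FALSE]
    stat <- drop(t(bn) %*% solve(Vn, bn))
    dof <- length(bn)
    p <- pchisq(stat, df = dof, lower.tail = FALSE)
    test <- "Wald"
  }
  chosen <- if (p < level) best else fits$linear
  sel <- list(
    ic = c(linear = fits$linear$ic, ics),
    best_spline = best$year_shape, test = test, statistic = stat,
    p_value = p, adopted = chosen$year_shape, warnings = warnings_log
  )
  attr(chosen, "selection") <- sel
  chosen
}
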