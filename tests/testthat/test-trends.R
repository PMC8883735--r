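# Trend-model tests use synthetic count tables at the study's cell layout
# (42 years x 4 age-sex strata) built directly in code.

test_that("negative binomial incidence fit recovers a known log-linear trend", {
  set.seed(101)
  slope <- 0.02
  tab <- make_count_table(function(year, g, s) {
    exp(-6 + slope * (year - 1995) + 0.3 * (g == "10-17") - 0.1 * (s == "M"))
  })
  fit <- fit_incidence(tab, "linear")
  est <- fit$coefficients["year1"]
  se <- sqrt(fit$vcov["year1", "year1"])
  expect_lt(abs(est - slope), 3 * se)
  # Poisson-generated data: little overdispersion, deviance ratio near 1
  expect_gt(fit$dispersion, 20)
  expect_lt(abs(fit$fit_stats$deviance_ratio - 1), 0.35)
  expect_equal(fit$fit_stats$residual_dof, nrow(tab) - 4L)
  # outcome variance exceeds the mean (NB)
  expect_true(all(fit$predictions$v >= fit$predictions$mu))
})

test_that("flat counts with equal offsets give a zero year coefficient", {
  tab <- make_count_table(function(year, g, s) rep(20 / 8000, length(year)),
    cohort = rep(8000L, 4), rdist = function(n, mu) rep(20L, n)
  )
  fit <- fit_incidence(tab, "linear")
  expect_lt(abs(fit$coefficients["year1"]), 1e-6)
})

test_that("the log-cohort offset enters the model exactly", {
  set.seed(102)
  tab <- make_count_table(function(year, g, s) exp(-6 + 0.01 * (year - 1995)))
  fit1 <- fit_incidence(tab, "rcs3")
  # at fixed coefficients, doubling the offset doubles every predicted mean
  mu_doubled <- exp(log(2 * tab$cohort_size) - log(tab$cohort_size)) *
    fit1$predictions$mu
  expect_lt(max(abs(mu_doubled / fit1$predictions$mu - 2)), 1e-12)
  # refitting with doubled cohorts shifts only the intercept, by -log(2),
  # and leaves the fitted means (same counts) unchanged
  tab2 <- tab
  tab2$cohort_size <- tab2$cohort_size * 2L
  fit2 <- fit_incidence(tab2, "rcs3")
  expect_lt(abs((fit2$coefficients[1] - fit1$coefficients[1]) + log(2)), 1e-6)
  expect_lt(max(abs(fit2$coefficients[-1] - fit1$coefficients[-1])), 1e-6)
  expect_lt(max(abs(fit2$predictions$mu - fit1$predictions$mu)), 1e-4)
})

test_that("predictions are invariant to shifting the year origin", {
  set.seed(103)
  tab <- make_count_table(function(year, g, s) {
    exp(-6 + 0.02 * (year - 1995) + 0.2 * sin((year - 1975) / 8))
  })
  fit1 <- fit_incidence(tab, "rcs4")
  tab_shift <- tab
  tab_shift$year <- tab_shift$year - 1000L
  fit2 <- fit_incidence(tab_shift, "rcs4")
  # equality up to the optimiser's convergence tolerance
  expect_lt(max(abs(fit1$predictions$mu - fit2$predictions$mu)), 1e-4)
})

test_that("spline deviance never exceeds linear deviance on the same data (nesting)", {
  set.seed(104)
  for (rep in 1:5) {
    tab <- make_count_table(function(year, g, s) {
      exp(-6.2 + 0.015 * (year - 1995) + 0.1 * (g == "10-17"))
    })
    lin <- fit_incidence(tab, "linear")
    spl <- fit_incidence(tab, "rcs5")
    expect_lte(spl$fit_stats$residual_deviance, lin$fit_stats$residual_deviance + 1e-8)
    lrt <- 2 * (spl$fit_stats$logLik - lin$fit_stats$logLik)
    expect_gte(lrt, -1e-6)
  }
})

test_that("Wald intervals for the year slope have near-nominal coverage", {
  # 100 replicates at the study cell count; 95% CIs should cover the true
  # slope 90-99 times
  set.seed(105)
  slope <- 0.015
  covered <- 0L
  for (r in 1:100) {
    tab <- make_count_table(function(year, g, s) {
      exp(-6 + slope * (year - 1995) + 0.25 * (g == "10-17"))
    })
    fit <- fit_incidence(tab, "linear")
    est <- fit$coefficients["year1"]
    se <- sqrt(fit$vcov["year1", "year1"])
    if (abs(est - slope) <= qnorm(0.975) * se) covered <- covered + 1L
  }
  expect_gte(covered, 90L)
  expect_lte(covered, 99L)
})

test_that("the estimating-equations fitter matches independence GLM when alpha is fixed at 0", {
  set.seed(106)
  tab <- make_count_table(function(year, g, s) exp(-6 + 0.01 * (year - 1995)))
  df <- as.data.frame(tab)
  df$age_group <- factor(df$age_group)
  df$sex <- factor(df$sex)
  df$cluster <- interaction(df$age_group, df$sex)
  df <- df[order(df$cluster, df$year), ]
  X <- model.matrix(~ age_group + sex + year, df)
  gee0 <- gee_ar1_poisson(df$case_count, X, offset = log(df$cohort_size),
    id = df$cluster, alpha_fix = 0)
  glm0 <- glm(case_count ~ age_group + sex + year + offset(log(cohort_size)),
    family = poisson(), data = df)
  expect_lt(max(abs(gee0$coefficients - coef(glm0))), 1e-6)
})

test_that("AR(1) estimate is near zero for independent data and recovers true correlation", {
  set.seed(107)
  alphas <- replicate(30, {
    tab <- make_count_table(function(year, g, s) exp(-6 + 0.01 * (year - 1995)))
    fit <- fit_prevalence(tab, "linear")
    fit$fit_stats$alpha
  })
  # moment estimator on independent Poisson data: mean alpha ~ 0
  expect_lt(abs(mean(alphas)), 3 * sd(alphas) / sqrt(length(alphas)))

  # strongly autocorrelated multiplicative noise pushes the estimate up:
  # AR(1) log-noise with sd 0.3 on means ~40 makes the serial component
  # dominate the Poisson component
  set.seed(108)
  years <- 1975:2016
  tab <- make_count_table(function(year, g, s) exp(-5.3), rdist = function(n, mu) {
    idx <- rep(seq_len(n %/% length(years)), length(years))  # stratum of each row
    out <- numeric(n)
    for (s in unique(idx)) {
      e <- as.numeric(arima.sim(list(ar = 0.9), length(years), sd = 0.3))
      out[idx == s] <- rpois(length(years), mu[idx == s] * exp(e))
    }
    out
  })
  fit <- fit_prevalence(tab, "linear")
  expect_gt(fit$fit_stats$alpha, 0.3)
})

test_that("QIC matches the brute-force recomputation and its trace identity", {
  set.seed(109)
  tab <- make_count_table(function(year, g, s) exp(-6 + 0.01 * (year - 1995)))
  fit <- fit_prevalence(tab, "rcs3")
  g <- fit$model
  expect_lt(abs(qic(g) - oracle_qic(g)), 1e-8)
  # with the robust covariance replaced by the inverse independence
  # information, the penalty collapses to 2p
  g2 <- g
  A_I <- crossprod(g$X * sqrt(g$fitted))
  g2$vcov_robust <- solve(A_I)
  mu <- g2$fitted
  q <- sum(ifelse(g2$y > 0, g2$y * log(mu), 0) - mu)
  expect_equal(qic(g2), -2 * q + 2 * ncol(g2$X), tolerance = 1e-10)
})

test_that("QIC prefers the generating model among nested candidates", {
  # with many clusters the sandwich-based penalty is stable and the
  # criterion behaves like an information criterion; at the study's four
  # clusters the robust covariance (hence the penalty) is noisy, so this
  # consistency property is checked at 20 clusters of 30 observations
  set.seed(110)
  wins <- 0L
  for (r in 1:50) {
    ncl <- 20L
    nt <- 30L
    id <- rep(seq_len(ncl), each = nt)
    t <- rep(seq_len(nt), ncl) / 10
    X_small <- cbind(intercept = 1, t = t)
    X_big <- cbind(X_small, t2 = t^2, t3 = t^3)
    mu <- exp(2 + 0.5 * t)
    y <- rpois(length(mu), mu)
    f_small <- gee_ar1_poisson(y, X_small, id = id)
    f_big <- gee_ar1_poisson(y, X_big, id = id)
    if (qic(f_small) < qic(f_big)) wins <- wins + 1L
  }
  expect_gte(wins, 40L) # >= 80% of 50 replicates
})

test_that("year-shape selection follows the IC + test rule", {
  set.seed(111)
  # near-noiseless sigmoidal trend: a spline must be adopted
  tab <- make_count_table(function(year, g, s) {
    exp(-6 + 1.2 * plogis((year - 1995) / 4))
  }, cohort = rep(50000L, 4))
  fit <- select_year_shape(tab, "incidence")
  sel <- attr(fit, "selection")
  expect_true(fit$year_shape %in% c("rcs3", "rcs4", "rcs5"))
  expect_lt(sel$p_value, 0.05)

  # prevalence path with the Wald test on the same strong nonlinearity
  fitp <- select_year_shape(tab, "prevalence")
  expect_true(fitp$year_shape %in% c("rcs3", "rcs4", "rcs5"))
  expect_equal(attr(fitp, "selection")$test, "Wald")

  # marginal R^2 near 1 on a near-noiseless trend
  expect_gt(fitp$fit_stats$marginal_r2, 0.95)
})
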