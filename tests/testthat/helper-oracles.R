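# Independent oracle implementations used to verify the package's
# operations. These deliberately use different algorithms (exhaustive
# enumeration, numerically solved constraints, explicit summation) from the
# code paths they check.

# Maximum number of visits >= `gap` days apart, by exhaustive subset search.
oracle_max_spaced <- function(dates, gap) {
  d <- sort(as.numeric(dates))
  n <- length(d)
  if (n == 0L) return(0L)
  if (gap <= 0) return(n)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- d[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(sel) <= best) next
    if (length(sel) <= 1L || all(diff(sel) >= gap)) best <- length(sel)
  }
  best
}

# Exhaustive anchor-scan case ascertainment, independent of ascertain_person.
# claims: data.frame with service_date (Date), setting; sorted by date.
oracle_ascertain <- function(claims, spec, lookback_years = 3L) {
  d <- as.numeric(claims$service_date)
  if (length(d) == 0L) return(NULL)
  hosp <- d[claims$setting == "hospital"]
  phys <- d[claims$setting == "physician"]
  wdays <- spec$window_years * 365 - 1
  for (a in d) {
    ok_h <- spec$min_hospital > 0 &&
      length(hosp[hosp >= a & hosp <= a + wdays]) >= spec$min_hospital
    pw <- phys[phys >= a & phys <= a + wdays]
    np <- if (spec$min_days_apart > 0) oracle_max_spaced(pw, spec$min_days_apart) else length(pw)
    ok_p <- np >= spec$min_physician
    if (ok_h || ok_p) {
      incident <- !any(d >= a - lookback_years * 365 & d < a)
      return(list(case_date = as.Date(a, origin = "1970-01-01"), incident = incident))
    }
  }
  NULL
}

# Restricted cubic spline basis via numerically solved tail-linearity
# constraints: column j is (x - t_j)^3_+ + a (x - t_{k-1})^3_+ + b (x - t_k)^3_+
# with (a, b) solving sum-of-cubic-coefficients = 0 and
# sum-of-coefficient-times-knot = 0, then scaled by (t_k - t_1)^-2.
oracle_rcs <- function(x, knots) {
  k <- length(knots)
  p3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    A <- rbind(c(1, 1), c(knots[k - 1], knots[k]))
    ab <- solve(A, c(-1, -knots[j]))
    out[, j + 1] <- (p3(x - knots[j]) + ab[1] * p3(x - knots[k - 1]) +
      ab[2] * p3(x - knots[k])) / (knots[k] - knots[1])^2
  }
  out
}

# Holm step-down adjustment by explicit loop over the sorted p-values.
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[ord[i]])
    running <- max(running, val)
    adj[ord[i]] <- running
  }
  adj
}

# Exact two-sided McNemar p-value by explicit binomial summation.
oracle_mcnemar_exact <- function(b, cc) {
  n <- b + cc
  if (n == 0L) return(1)
  tail <- sum(choose(n, 0:min(b, cc))) / 2^n
  min(1, 2 * tail)
}

# QIC recomputed by explicit per-observation summation.
oracle_qic <- function(fit) {
  mu <- fit$fitted
  y <- fit$y
  q <- 0
  for (i in seq_along(y)) {
    q <- q + (if (y[i] > 0) y[i] * log(mu[i]) else 0) - mu[i]
  }
  p <- ncol(fit$X)
  A <- matrix(0, p, p)
  for (i in seq_along(y)) {
    xi <- fit$X[i, ]
    A <- A + mu[i] * tcrossprod(xi)
  }
  pen <- 0
  AV <- A %*% fit$vcov_robust
  for (i in seq_len(p)) pen <- pen + AV[i, i]
  -2 * q + 2 * pen
}

# A synthetic stratum count table for trend-model tests (not from the
# claims simulator): counts drawn around a known log-linear or user-given
# mean structure.
make_count_table <- function(mu_fun, years = 1975:2016,
                             cohort = c(8000, 8200, 7800, 8100),
                             rdist = function(n, mu) rpois(n, mu),
                             outcome = "incidence", algorithm = "synthetic") {
  grid <- expand.grid(
    sex = c("F", "M"), age_group = c("0-9", "10-17"), year = years,
    stringsAsFactors = FALSE
  )[, c("year", "age_group", "sex")]
  grid <- grid[order(grid$year, grid$age_group, grid$sex), ]
  rownames(grid) <- NULL
  stratum <- as.integer(factor(paste(grid$age_group, grid$sex)))
  grid$cohort_size <- cohort[stratum]
  mu <- mu_fun(grid$year, grid$age_group, grid$sex) * grid$cohort_size
  grid$case_count <- rdist(nrow(grid), mu)
  grid$suppressed <- grid$case_count > 0 & grid$case_count < 6
  structure(grid,
    class = c("count_table", "data.frame"),
    algorithm = algorithm, outcome = outcome, study_span = range(years)
  )
}
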