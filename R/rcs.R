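#' Restricted cubic spline basis with knots at recommended quantiles
#'
#' Builds the restricted (natural) cubic spline basis in truncated-power
#' form: a linear column plus `n_knots - 2` restricted cubic columns, each
#' constrained to be linear beyond the boundary knots and normalized by the
#' squared knot range so coefficients stay on a comparable scale. Knots are
#' placed at the quantiles of the observed values recommended by Harrell:
#' `{.10, .50, .90}` for 3 knots, `{.05, .35, .65, .95}` for 4, and
#' `{.05, .275, .50, .725, .95}` for 5.
#'
#' @param years numeric vector of observed values (calendar years).
#' @param n_knots number of knots, 3--5.
#' @param knots optional explicit knot locations (overrides the quantile rule).
#' @return an `rcs_basis`: list with `knots` and `basis` (matrix with
#'   `n_knots - 1` columns named `year1`, `year2`, ...).
#' @export
rcs_basis <- function(years, n_knots = 3L, knots = NULL) {
  if (is.null(knots)) {
    if (!n_knots %in% 3:5) stop("n_knots must be 3, 4 or 5")
    if (length(unique(years)) < n_knots) {
      stop("need at least ", n_knots, " distinct values to place ", n_knots, " knots")
    }
    probs <- switch(as.character(n_knots),
      "3" = c(.10, .50, .90),
      "4" = c(.05, .35, .65, .95),
      "5" = c(.05, .275, .50, .725, .95)
    )
    knots <- as.numeric(quantile(years, probs, type = 7, names = FALSE))
  }
  knots <- sort(knots)
  if (anyDuplicated(knots)) stop("knot locations must be distinct")
  basis <- rcs_eval(years, knots)
  structure(list(knots = knots, basis = basis), class = "rcs_basis")
}

#' Evaluate the restricted cubic spline basis at arbitrary points
#'
#' @param x points at which to evaluate.
#' @param knots ordered knot locations (length k >= 3).
#' @return matrix with `k - 1` columns: `x` itself, then the restricted
#'   truncated-power terms normalized by `(t_k - t_1)^2`.
#' @export
rcs_eval <- function(x, knots) {
  k <- length(knots)
  if (k < 3L) stop("need at least 3 knots")
  t1 <- knots[1]
  tk <- knots[k]
  tk1 <- knots[k - 1]
  norm <- (tk - t1)^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1L)
  out[, 1] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (pos3(x - tj) -
      pos3(x - tk1) * (tk - tj) / (tk - tk1) +
      pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- paste0("year", seq_len(k - 1L))
  out
}
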