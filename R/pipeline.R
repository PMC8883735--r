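#' Configuration for an end-to-end stability study
#'
#' @param sim a [sim_config()] describing the synthetic dataset (ignored
#'   when `data` is supplied to [run_study()]).
#' @param algorithms character vector of algorithm names (default: all 18
#'   juvenile diabetes definitions).
#' @param study_span `(first_year, last_year)` for counting and charts.
#' @param k_values control-limit multipliers (0.8 main, 2 sensitivity).
#' @param reference reference algorithm for stability comparisons.
#' @param seed master seed for imputation (and simulation when `sim` lacks one).
#' @param out_dir optional directory: when set, [run_study()] writes CSV/JSON
#'   outputs there.
#' @return a `study_config`.
#' @export
study_config <- function(sim = sim_config(),
                         algorithms = juvenile_diabetes_algorithms(),
                         study_span = c(1975L, 2016L),
                         k_values = c(0.8, 2),
                         reference = "2: 1 + H or 1 + P",
                         seed = 1L,
                         out_dir = NULL) {
  cfg <- list(
    sim = sim, algorithms = algorithms, study_span = as.integer(study_span),
    k_values = k_values, reference = reference, seed = as.integer(seed),
    out_dir = out_dir
  )
  class(cfg) <- "study_config"
  errs <- character(0)
  for (a in cfg$algorithms) {
    tryCatch(parse_algorithm_name(a), error = function(e) {
      errs <<- c(errs, conditionMessage(e))
    })
  }
  if (!cfg$reference %in% cfg$algorithms) {
    errs <- c(errs, "reference algorithm must be in the algorithm list")
  }
  if (any(cfg$k_values <= 0)) errs <- c(errs, "k values must be positive")
  if (cfg$study_span[1] > cfg$study_span[2]) {
    errs <- c(errs, "study_span must be (first_year, last_year) in order")
  }
  if (length(errs)) stop("invalid study configuration:\n  ", paste(errs, collapse = "\n  "))
  cfg
}

#' Validate a raw configuration document
#'
#' Accepts a plain list (e.g. parsed from YAML), fills defaults, validates
#' algorithm names against the grammar, and aggregates all errors into one
#' report.
#'
#' @param raw named list; recognized fields: `algorithms`, `study_span`,
#'   `k_values`, `reference`, `seed`, `sim` (sub-list passed to
#'   [sim_config()]), `out_dir`.
#' @return a validated `study_config`.
#' @export
validate_config <- function(raw = list()) {
  if (!is.list(raw)) stop("configuration document must parse to a list")
  sim <- if (is.null(raw$sim)) sim_config() else do.call(sim_config, raw$sim)
  study_config(
    sim = sim,
    algorithms = raw$algorithms %||% juvenile_diabetes_algorithms(),
    study_span = raw$study_span %||% c(1975L, 2016L),
    k_values = raw$k_values %||% c(0.8, 2),
    reference = raw$reference %||% "2: 1 + H or 1 + P",
    seed = raw$seed %||% 1L,
    out_dir = raw$out_dir
  )
}

#' Run the full trend-stability study
#'
#' For each algorithm: ascertain cases, build incident and prevalent count
#' tables, apply the suppression rule (exclude when more than 10% of cells
#' are suppressed, impute otherwise), select the year-effect shape for each
#' outcome, and build observed-expected control charts at each control-limit
#' multiplier. Then compares each modelled algorithm's out-of-control series
#' with the reference by McNemar tests within period families
#' (Holm-Bonferroni adjusted) and computes agreement-by-year and crude-rate
#' period summaries.
#'
#' @param config a `study_config`.
#' @param data optional pre-simulated `sim_study` (or list with `registry`
#'   and `claims`); when `NULL` the dataset is simulated from `config$sim`.
#' @return a `study_result`: list with `counts`, `fits`, `charts`,
#'   `stability`, `agreement`, `rates`, and a `manifest` recording
#'   inclusions, exclusions, model selections and warnings.
#' @export
run_study <- function(config = study_config(), data = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(data)) data <- simulate_study(config$sim)
  registry <- data$registry
  claims <- data$claims
  span <- config$study_span

  counts <- list()
  fits <- list()
  charts <- list()
  manifest <- list(
    seed = config$seed, algorithms = config$algorithms,
    reference = config$reference, k_values = config$k_values,
    study_span = span, exclusions = list(), selections = list(),
    warnings = character(0), outputs = character(0)
  )

  cache <- study_cache(registry, claims)
  for (alg in config$algorithms) {
    tabs <- build_count_tables(registry, claims, alg, span, cache = cache)
    for (outcome in c("incidence", "prevalence")) {
      tab <- if (outcome == "incidence") tabs$incident else tabs$prevalent
      supp <- apply_suppression_and_imputation(tab, config$seed)
      key <- paste(alg, outcome, sep = " | ")
      counts[[key]] <- supp$table
      if (supp$excluded) {
        manifest$exclusions[[key]] <- sprintf(
          "suppressed fraction %.3f exceeds 0.10", supp$suppressed_fraction
        )
        next
      }
      fit <- tryCatch(
        withCallingHandlers(
          select_year_shape(supp$table, outcome),
          warning = function(w) {
            manifest$warnings <<- c(
              manifest$warnings,
              paste0(key, ": ", conditionMessage(w))
            )
            invokeRestart("muffleWarning")
          }
        ),
        error = function(e) {
          manifest$exclusions[[key]] <<- paste("model failure:", conditionMessage(e))
          NULL
        }
      )
      if (is.null(fit)) next
      fits[[key]] <- fit
      manifest$selections[[key]] <- attr(fit, "selection")[c("adopted", "best_spline", "p_value")]
      for (k in config$k_values) {
        charts[[paste(key, k, sep = " | ")]] <- build_chart(fit, k)
      }
    }
  }

  ref_keys <- paste(config$reference, c("incidence", "prevalence"), sep = " | ")
  if (!any(ref_keys %in% names(fits))) {
    stop(
      "reference algorithm ", sQuote(config$reference),
      " was excluded from modelling; choose another reference"
    )
  }

  stability <- list()
  agreement <- list()
  for (outcome in c("incidence", "prevalence")) {
    for (k in config$k_values) {
      keys <- names(fits)[endsWith(names(fits), paste0(" | ", outcome))]
      series <- lapply(keys, function(kk) {
        ooc_series(charts[[paste(kk, k, sep = " | ")]])
      })
      names(series) <- sub(" \\|.*$", "", keys)
      skey <- paste(outcome, k, sep = " | k=")
      agreement[[skey]] <- agreement_by_year(series)
      refnm <- config$reference
      if (refnm %in% names(series)) {
        others <- series[setdiff(names(series), refnm)]
        stability[[skey]] <- compare_all(series[[refnm]], others)
        props <- vapply(series, ooc_proportion, numeric(1))
        stability[[skey]] <- list(
          comparisons = stability[[skey]],
          ooc_proportions = data.frame(
            algorithm = names(props),
            ooc_count = vapply(series, sum, numeric(1)),
            ooc_proportion = unname(props)
          )
        )
      }
    }
  }

  rates <- list()
  for (key in names(fits)) {
    rates[[key]] <- rate_summary(counts[[key]])$periods
  }

  result <- structure(
    list(
      counts = counts, fits = fits, charts = charts, stability = stability,
      agreement = agreement, rates = rates, manifest = manifest,
      config = config
    ),
    class = "study_result"
  )
  if (!is.null(config$out_dir)) write_study_result(result, config$out_dir)
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat(
    "<study_result>", length(x$config$algorithms), "algorithms;",
    length(x$fits), "modelled algorithm-outcomes;",
    length(x$manifest$exclusions), "excluded\n"
  )
  for (nm in names(x$manifest$exclusions)) {
    cat("  excluded:", nm, "-", x$manifest$exclusions[[nm]], "\n")
  }
  invisible(x)
}

# Write CSV/JSON outputs for a study run.
write_study_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  safe <- function(s) gsub("[^A-Za-z0-9.-]+", "_", s)
  for (key in names(result$charts)) {
    p <- file.path(dir, paste0("chart_", safe(key), ".csv"))
    write.csv(as.data.frame(result$charts[[key]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (key in names(result$stability)) {
    p <- file.path(dir, paste0("stability_", safe(key), ".csv"))
    write.csv(result$stability[[key]]$comparisons, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (key in names(result$agreement)) {
    p <- file.path(dir, paste0("agreement_", safe(key), ".csv"))
    ag <- result$agreement[[key]]
    write.csv(data.frame(year = names(ag), agreement = unname(ag)), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  result$manifest$outputs <- paths
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    mp <- file.path(dir, "manifest.json")
    jsonlite::write_json(result$manifest, mp, auto_unbox = TRUE, digits = NA, force = TRUE)
    paths <- c(paths, mp)
  }
  invisible(paths)
}
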