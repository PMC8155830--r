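#' Assemble a pipeline configuration
#'
#' A configuration either names the three input tables (`panel_path`,
#' `geo_path`, `census_path` plus a column `dialect`) or carries a
#' [synthetic_config()] under `synthetic`. Window, neighborhood, AR and
#' scenario settings parameterize the downstream stages.
#'
#' @param synthetic optional `synthetic_config`; when present the three
#'   tables are generated instead of read.
#' @param panel_path,geo_path,census_path input CSV paths (ignored when
#'   `synthetic` is given).
#' @param dialect drug-report column dialect, see [read_drug_reports()].
#' @param opioid_set substance names counted as opioids (defaults to the
#'   synthetic config's opioid substances when generating).
#' @param years_mean,early,late indicator year windows; defaults derived
#'   from the data's year range (full range; first and second half).
#' @param k neighborhood size.
#' @param ar_order,horizon forecasting settings.
#' @param scenarios list of [policy_scenario()] objects.
#' @param n_levels severity levels.
#' @param out_dir output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, panel_path = NULL,
                            geo_path = NULL, census_path = NULL,
                            dialect = default_dialect(),
                            opioid_set = NULL,
                            years_mean = NULL, early = NULL, late = NULL,
                            k = 5, ar_order = 2, horizon = 4,
                            scenarios = list(), n_levels = 6,
                            out_dir = "ewmrsr-output") {
  if (is.null(synthetic) &&
      (is.null(panel_path) || is.null(geo_path) || is.null(census_path)))
    stop("either a synthetic config or all three input paths are required")
  structure(list(synthetic = synthetic, panel_path = panel_path,
                 geo_path = geo_path, census_path = census_path,
                 dialect = dialect, opioid_set = opioid_set,
                 years_mean = years_mean, early = early, late = late,
                 k = k, ar_order = ar_order, horizon = horizon,
                 scenarios = scenarios, n_levels = n_levels,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments;
#' `synthetic` (a mapping of [synthetic_config()] arguments, with
#' `planted_beta` as nested code-to-coefficient mappings) and `scenarios`
#' (a sequence of [policy_scenario()] argument mappings) are built
#' recursively.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    if (!is.null(s$years)) s$years <- s$years[1]:s$years[length(s$years)]
    if (!is.null(s$cluster_centers))
      s$cluster_centers <- do.call(rbind, s$cluster_centers)
    if (!is.null(s$planted_beta))
      s$planted_beta <- lapply(s$planted_beta, unlist)
    y$synthetic <- do.call(synthetic_config, s)
  }
  if (!is.null(y$scenarios))
    y$scenarios <- lapply(y$scenarios, function(sc)
      do.call(policy_scenario, sc))
  for (w in c("years_mean", "early", "late"))
    if (!is.null(y[[w]])) y[[w]] <- y[[w]][1]:y[[w]][length(y[[w]])]
  do.call(pipeline_config, y)
}

# default year windows from the observed range: full span, split in half
.default_windows <- function(years) {
  yrs <- sort(unique(years))
  half <- length(yrs) %/% 2
  list(years_mean = yrs, early = yrs[seq_len(max(half, 1))],
       late = yrs[(half + 1):length(yrs)])
}

#' Run the complete severity pipeline
#'
#' Loads (or generates) the three input tables, computes the four spread
#' indicators, fits the entropy-weight rank-sum-ratio evaluation, forecasts
#' severity with county-level AR models, fits the per-indicator LASSO
#' models on the census table, and simulates any configured policy
#' scenarios. All artifacts are written as CSV under `config$out_dir`
#' together with a YAML run manifest; outputs are deterministic given the
#' configuration (and its seed).
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress per-stage progress messages.
#' @return Invisibly, a list with every intermediate object (`panel`,
#'   `geo`, `census`, `indicators`, `ewm`, `forecast`, `comprehensive`,
#'   `ewm_comprehensive`, `trajectories`) and the output directory.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[ewmrsr] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$synthetic)) {
      say("generating synthetic dataset (seed ", config$synthetic$seed, ")")
      ds <- generate_dataset(config$synthetic, k = config$k)
      panel <- ds$panel; geo <- ds$geo; census <- ds$census
      states <- ds$states
      opioid_set <- config$opioid_set %||% config$synthetic$opioid_substances
    } else {
      say("reading input tables")
      panel <- read_drug_reports(config$panel_path, config$dialect)
      geo <- read_geo(config$geo_path)
      census <- read_census(config$census_path)
      states <- stats::setNames(
        panel$records$state[match(unique(panel$records$fips),
                                  panel$records$fips)],
        unique(panel$records$fips))
      opioid_set <- config$opioid_set
      if (is.null(opioid_set)) stop("opioid substance list is required")
    }
    w <- .default_windows(panel$tdrc$year)
    years_mean <- config$years_mean %||% w$years_mean
    early <- config$early %||% w$early
    late <- config$late %||% w$late

    stage <- "spread indicators"
    say("computing spread indicators (k = ", config$k, ")")
    ind <- compute_indicators(panel, geo, opioid_set,
                              years_mean = years_mean, early = early,
                              late = late, k = config$k)
    write_results(ind, file.path(config$out_dir, "indicators.csv"))

    stage <- "EWM-RSR evaluation"
    say("fitting EWM-RSR evaluation")
    ewm <- ewm_rsr_fit(ind, n_levels = config$n_levels)
    write_results(ewm$result, file.path(config$out_dir, "evaluation.csv"))
    write_results(data.frame(indicator = names(ewm$weights),
                             entropy = as.numeric(ewm$entropy),
                             weight = as.numeric(ewm$weights)),
                  file.path(config$out_dir, "weights.csv"))

    stage <- "AR forecast"
    say("forecasting severity ", config$horizon, " years ahead (AR(",
        config$ar_order, "))")
    fc <- forecast_severity(panel, geo, ewm, opioid_set,
                            years_mean = years_mean, early = early,
                            late = late, k = config$k,
                            p = config$ar_order, horizon = config$horizon)
    write_results(fc, file.path(config$out_dir, "forecast.csv"))

    stage <- "comprehensive LASSO"
    say("fitting per-indicator LASSO models (LOOCV)")
    census_imp <- impute_missing(census)
    cfit <- fit_comprehensive(census_imp, ind)
    coefs <- do.call(rbind, lapply(names(cfit$fits), function(nm) {
      f <- cfit$fits[[nm]]
      data.frame(indicator = nm, lambda = f$lambda,
                 code = names(f$fit$beta), beta = as.numeric(f$fit$beta),
                 stringsAsFactors = FALSE)
    }))
    write_results(coefs, file.path(config$out_dir, "lasso_fits.csv"))
    comp <- modify_indicators(cfit, ind)
    write_results(comp, file.path(config$out_dir,
                                  "comprehensive_indicators.csv"))
    ewm_comp <- ewm_rsr_fit(comp, n_levels = config$n_levels)

    stage <- "policy simulation"
    trajectories <- list()
    for (si in seq_along(config$scenarios)) {
      sc <- config$scenarios[[si]]
      say("simulating policy scenario ", si, " (reduction ",
          sc$reduction * 100, "%, alpha ", sc$alpha, ")")
      tr <- simulate_policy(sc, cfit, ind, ewm_comp, census_imp,
                            groups = states)
      trajectories[[si]] <- tr
      write_results(tr, file.path(config$out_dir,
                                  sprintf("scenario_%02d.csv", si)))
    }

    manifest <- list(
      package = "ewmrsr",
      version = as.character(utils::packageVersion("ewmrsr")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = if (!is.null(config$synthetic)) config$synthetic$seed else NA,
      k = config$k, ar_order = config$ar_order, horizon = config$horizon,
      years_mean = range(years_mean), early = range(early),
      late = range(late), n_levels = config$n_levels,
      opioid_set = opioid_set,
      n_counties = nrow(ind),
      scenarios = lapply(config$scenarios, function(sc)
        sc[c("target_codes", "reduction", "alpha", "periods",
             "aggregation")]))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

    list(panel = panel, geo = geo, census = census, indicators = ind,
         ewm = ewm, forecast = fc, comprehensive = cfit,
         comprehensive_indicators = comp, ewm_comprehensive = ewm_comp,
         trajectories = trajectories, out_dir = config$out_dir)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
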