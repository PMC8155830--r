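# run an expression with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Configuration for the synthetic surveillance-data generator
#'
#' Defines a synthetic study: counties scattered around cluster centers,
#' yearly drug-report counts with negative-binomial dispersion, a rising
#' opioid share in a planted subset of "severe" counties, and census
#' demographic columns linearly linked to the severity indicators through
#' sparse planted coefficients. The planted structure gives every
#' downstream stage a known ground truth.
#'
#' @param n_counties number of counties.
#' @param years inclusive year range (default 2010:2017, an 8-year panel).
#' @param substances names of non-opioid substances reported.
#' @param opioid_substances names of opioid substances.
#' @param opioid_fraction_base baseline opioid share of county drug
#'   reports, in (0, 1).
#' @param trend_slope_range interval from which each county's yearly
#'   multiplicative opioid-share trend is drawn.
#' @param cluster_centers matrix of (lat, lon) rows; counties are assigned
#'   round-robin and jittered around their center.
#' @param cluster_sd Gaussian jitter of county centroids, degrees.
#' @param dispersion negative-binomial size parameter of the yearly total
#'   drug-report counts (smaller = more overdispersed).
#' @param mean_reports mean yearly total drug reports of a typical county.
#' @param n_severe number of planted severe counties (high level, maximal
#'   trend, elevated opioid share), spread across clusters.
#' @param census_codes ACS-style variable codes of the census table.
#' @param planted_beta named list (`rho`, `q`, `Q`, `lofc`) of named
#'   sparse coefficient vectors over `census_codes` linking normalized
#'   census columns to each indicator.
#' @param noise_sd Gaussian noise on the planted census-indicator link.
#' @param seed integer seed; all generation is deterministic given it.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_counties = 100,
                             years = 2010:2017,
                             substances = c("cocaine", "methamphetamine",
                                            "cannabis", "alprazolam",
                                            "buprenorphine"),
                             opioid_substances = c("heroin", "oxycodone",
                                                   "fentanyl"),
                             opioid_fraction_base = 0.25,
                             trend_slope_range = c(-0.03, 0.12),
                             cluster_centers = rbind(c(37.5, -78.5),
                                                     c(40.9, -77.8),
                                                     c(37.8, -84.3),
                                                     c(40.4, -82.8),
                                                     c(38.6, -80.5)),
                             cluster_sd = 0.6,
                             dispersion = 5,
                             mean_reports = 500,
                             n_severe = 5,
                             census_codes = paste0("HC03_VC", 101:120),
                             planted_beta = list(
                               rho = c(HC03_VC112 = 0.5, HC03_VC114 = 0.3,
                                       HC03_VC115 = 0.2),
                               q = c(HC03_VC103 = 0.6),
                               Q = c(HC03_VC101 = -0.4, HC03_VC112 = 0.4),
                               lofc = c(HC03_VC114 = 0.7)),
                             noise_sd = 0.05,
                             seed = 42) {
  if (n_counties < 1) stop("n_counties must be >= 1")
  if (opioid_fraction_base < 0 || opioid_fraction_base >= 1)
    stop("opioid_fraction_base must be in [0, 1)")
  if (diff(range(years)) + 1 != length(years))
    stop("years must be a contiguous range")
  if (trend_slope_range[1] > trend_slope_range[2])
    stop("degenerate trend_slope_range")
  if (dispersion <= 0) stop("dispersion must be > 0")
  bad <- setdiff(unlist(lapply(planted_beta, names)), census_codes)
  if (length(bad) > 0)
    stop("planted_beta references unknown census code: ", bad[1])
  if (!all(names(planted_beta) %in% c("rho", "q", "Q", "lofc")))
    stop("planted_beta keys must be among rho, q, Q, lofc")
  structure(list(n_counties = n_counties, years = years,
                 substances = substances,
                 opioid_substances = opioid_substances,
                 opioid_fraction_base = opioid_fraction_base,
                 trend_slope_range = trend_slope_range,
                 cluster_centers = cluster_centers, cluster_sd = cluster_sd,
                 dispersion = dispersion, mean_reports = mean_reports,
                 n_severe = min(n_severe, n_counties),
                 census_codes = census_codes, planted_beta = planted_beta,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_config")
}

# deterministic county ids, cluster and state assignment
.synthetic_layout <- function(config) {
  n <- config$n_counties
  fips <- sprintf("%05d", seq_len(n))
  ncl <- nrow(config$cluster_centers)
  cluster <- rep_len(seq_len(ncl), n)
  states <- rep_len(c("VA", "PA", "KY", "OH", "WV"), ncl)[cluster]
  severe <- fips[seq_len(config$n_severe)]
  list(fips = fips, cluster = cluster, states = states, severe = severe)
}

#' Generate synthetic county centroids
#'
#' Counties are assigned round-robin to the configured cluster centers and
#' jittered with isotropic Gaussian noise, producing the spatial
#' clustering the neighbor odds-ratio indicator assumes.
#'
#' @param config a `synthetic_config`.
#' @return `county_geo` table with attributes `state` (named FIPS-to-state
#'   vector) and `severe` (FIPS of the planted severe counties).
#' @export
generate_geo <- function(config) {
  lay <- .synthetic_layout(config)
  geo <- .with_seed(config$seed, {
    lat <- config$cluster_centers[lay$cluster, 1] +
      stats::rnorm(config$n_counties, 0, config$cluster_sd)
    lon <- config$cluster_centers[lay$cluster, 2] +
      stats::rnorm(config$n_counties, 0, config$cluster_sd)
    county_geo(lay$fips, pmin(pmax(lat, -90), 90),
               pmin(pmax(lon, -180), 180))
  })
  attr(geo, "state") <- stats::setNames(lay$states, lay$fips)
  attr(geo, "severe") <- lay$severe
  geo
}

#' Generate a synthetic drug-report panel
#'
#' Yearly total county drug reports are negative-binomial around a
#' county-specific level (log-normal across counties; tripled in severe
#' counties). The opioid share of each county-year is the configured base
#' share scaled by the county's yearly trend, so severe counties (drawn at
#' the top of the trend range) show a rising opioid share; totals are then
#' split binomially into opioid and non-opioid reports and multinomially
#' across substances. The result satisfies every panel invariant.
#'
#' @param config a `synthetic_config`.
#' @param geo the `county_geo` from [generate_geo()] (carries the state
#'   and severe-county assignment).
#' @return A validated `drug_panel`, with attribute `severe`.
#' @export
generate_panel <- function(config, geo) {
  lay <- .synthetic_layout(config)
  if (!all(lay$fips %in% geo$fips))
    stop("geo table does not cover the configured counties")
  n <- config$n_counties
  yrs <- config$years
  panel <- .with_seed(config$seed + 1, {
    level <- config$mean_reports *
      stats::rlnorm(n, meanlog = -0.245, sdlog = 0.7)
    slope <- stats::runif(n, config$trend_slope_range[1],
                          config$trend_slope_range[2])
    share0 <- rep(config$opioid_fraction_base, n)
    sev <- lay$fips %in% lay$severe
    level[sev] <- level[sev] * 3
    slope[sev] <- config$trend_slope_range[2]
    share0[sev] <- pmin(share0[sev] * 1.6, 0.9)
    subs <- c(config$opioid_substances, config$substances)
    n_op <- length(config$opioid_substances)
    rec_list <- vector("list", n * length(yrs))
    tdrc <- expand.grid(fips = lay$fips, year = yrs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tdrc$tdrc <- NA_real_
    idx <- 0L
    for (ci in seq_len(n)) {
      for (ti in seq_along(yrs)) {
        idx <- idx + 1L
        tot <- stats::rnbinom(1, size = config$dispersion, mu = level[ci])
        share <- min(max(share0[ci] * (1 + slope[ci] * (ti - 1)), 0), 0.95)
        n_opioid <- stats::rbinom(1, tot, share)
        op_split <- if (n_op > 0)
          as.integer(stats::rmultinom(1, n_opioid, rep(1, n_op))) else integer(0)
        rest <- tot - n_opioid
        other_split <- as.integer(stats::rmultinom(
          1, rest, rep(1, length(config$substances))))
        rec_list[[idx]] <- data.frame(
          fips = lay$fips[ci], state = lay$states[ci],
          county = paste0("County", lay$fips[ci]), year = yrs[ti],
          substance = subs, dr = c(op_split, other_split),
          stringsAsFactors = FALSE)
        tdrc$tdrc[tdrc$fips == lay$fips[ci] & tdrc$year == yrs[ti]] <- tot
      }
    }
    records <- do.call(rbind, rec_list)
    tots <- stats::aggregate(tdrc$tdrc,
                             by = list(state = lay$states[match(tdrc$fips,
                                                                lay$fips)],
                                       year = tdrc$year), FUN = sum)
    names(tots)[3] <- "tdrs"
    drug_panel(records, tdrc, tots)
  })
  attr(panel, "severe") <- lay$severe
  panel
}

#' Generate a synthetic census table linked to the indicators
#'
#' Census columns outside the planted supports are independent
#' beta-distributed percents. For each indicator with a planted
#' coefficient vector, all support columns but one are sampled freely and
#' the remaining one is solved from the linear relation
#' y* = beta' x* + noise (y* the min-max normalized indicator), then
#' rescaled onto \[0, 100\]. The rescaling is affine per column, so the
#' planted relation is preserved up to column-wise affine maps: signs and
#' supports are exact, and with `noise_sd = 0` a single-coefficient link
#' is a perfect correlation.
#'
#' @param config a `synthetic_config`.
#' @param indicators the `indicator_table` computed from the generated
#'   panel.
#' @return A `census_table` with one row per county.
#' @export
generate_census <- function(config, indicators) {
  n <- nrow(indicators)
  codes <- config$census_codes
  bad <- setdiff(unlist(lapply(config$planted_beta, names)), codes)
  if (length(bad) > 0)
    stop("planted_beta references unknown census code: ", bad[1])
  .with_seed(config$seed + 2, {
    vals <- matrix(stats::rbeta(n * length(codes), 2, 5) * 100,
                   nrow = n, dimnames = list(indicators$fips, codes))
    for (nm in names(config$planted_beta)) {
      beta <- config$planted_beta[[nm]]
      beta <- beta[beta != 0]
      if (length(beta) == 0) next
      y <- indicators[[nm]]
      ry <- range(y)
      ystar <- if (diff(ry) == 0) rep(0, n) else (y - ry[1]) / diff(ry)
      u <- ystar + stats::rnorm(n, 0, config$noise_sd)
      sup <- names(beta)
      free <- sup[-1]
      zsum <- 0
      for (j in free) {
        z <- stats::runif(n)
        vals[, j] <- z * 100
        zsum <- zsum + beta[j] * z
      }
      raw <- (u - zsum) / beta[sup[1]]
      rr <- range(raw)
      vals[, sup[1]] <- if (diff(rr) == 0) 50 else
        (raw - rr[1]) / diff(rr) * 100
    }
    census_table(pmin(pmax(vals, 0), 100))
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper producing coordinates, a drug-report panel, the
#' indicator table and a linked census table from one configuration.
#'
#' @param config a `synthetic_config`.
#' @param k neighborhood size for the indicators (capped at n - 1).
#' @return List with `geo`, `panel`, `indicators`, `census`, `states`
#'   (named FIPS-to-state vector) and `severe` (planted severe FIPS).
#' @export
generate_dataset <- function(config, k = 5) {
  geo <- generate_geo(config)
  panel <- generate_panel(config, geo)
  yrs <- config$years
  half <- length(yrs) %/% 2
  ind <- compute_indicators(panel, geo, config$opioid_substances,
                            years_mean = yrs,
                            early = yrs[seq_len(half)],
                            late = yrs[(half + 1):length(yrs)],
                            k = min(k, config$n_counties - 1))
  census <- generate_census(config, ind)
  list(geo = geo, panel = panel, indicators = ind, census = census,
       states = attr(geo, "state"), severe = attr(geo, "severe"))
}
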