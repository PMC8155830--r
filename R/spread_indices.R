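#' Yearly opioid share of a county's drug reports
#'
#' The proportion of opioid identification reports among all drug reports
#' of a county in one year: sum of opioid substance counts divided by the
#' total county drug reports. When the county reported no drugs at all in
#' that year the share is defined as 0.
#'
#' @param panel a `drug_panel`.
#' @param county county FIPS.
#' @param year calendar year.
#' @param opioid_set character vector of substance names counted as
#'   opioids.
#' @return Share in \[0, 1\].
#' @export
rho_yearly <- function(panel, county, year, opioid_set) {
  county <- pad_fips(county)
  idx <- panel$tdrc$fips == county & panel$tdrc$year == year
  if (!any(idx))
    stop("county-year (", county, ", ", year, ") absent from panel")
  tot <- panel$tdrc$tdrc[idx][1]
  if (tot == 0) return(0)
  rec <- panel$records
  sel <- rec$fips == county & rec$year == year & rec$substance %in% opioid_set
  sum(rec$dr[sel]) / tot
}

#' Mean opioid share over a year window
#'
#' Arithmetic mean of [rho_yearly()] over the (inclusive) window; each
#' year carries weight 1/window length.
#'
#' @inheritParams rho_yearly
#' @param years integer vector of years (e.g. `2010:2017`).
#' @return Mean share in \[0, 1\].
#' @export
rho_mean <- function(panel, county, years, opioid_set) {
  if (length(years) == 0) stop("empty year window")
  mean(vapply(years, function(t) rho_yearly(panel, county, t, opioid_set),
              numeric(1)))
}

# per-year opioid totals for one county, as a named numeric vector
.opioid_yearly <- function(panel, county, years, opioid_set) {
  county <- pad_fips(county)
  rec <- panel$records
  out <- stats::setNames(numeric(length(years)), years)
  sel <- rec$fips == county & rec$year %in% years &
    rec$substance %in% opioid_set
  if (any(sel)) {
    s <- tapply(rec$dr[sel], rec$year[sel], sum)
    out[names(s)] <- s
  }
  out
}

#' Average yearly change rate of opioid report counts
#'
#' The difference between the mean yearly opioid count in a late window
#' and an early window, divided by the difference of the windows' mean
#' years. With the default windows 2010-2013 vs 2014-2017 the denominator
#' is 4 years.
#'
#' @inheritParams rho_yearly
#' @param early,late integer year vectors for the two windows.
#' @return Change rate in reports per year.
#' @export
q_rate <- function(panel, county, early, late, opioid_set) {
  if (length(early) == 0 || length(late) == 0) stop("empty year window")
  denom <- mean(late) - mean(early)
  if (denom == 0) stop("windows have identical mean years")
  e <- mean(.opioid_yearly(panel, county, early, opioid_set))
  l <- mean(.opioid_yearly(panel, county, late, opioid_set))
  (l - e) / denom
}

#' Average yearly change rate of the opioid share
#'
#' As [q_rate()] but on the yearly opioid share instead of the raw count:
#' a positive value means drug users in the county increasingly prefer
#' opioids.
#'
#' @inheritParams q_rate
#' @return Change rate in share units per year.
#' @export
Q_rate <- function(panel, county, early, late, opioid_set) {
  if (length(early) == 0 || length(late) == 0) stop("empty year window")
  denom <- mean(late) - mean(early)
  if (denom == 0) stop("windows have identical mean years")
  e <- mean(vapply(early, function(t) rho_yearly(panel, county, t, opioid_set),
                   numeric(1)))
  l <- mean(vapply(late, function(t) rho_yearly(panel, county, t, opioid_set),
                   numeric(1)))
  (l - e) / denom
}

#' Great-circle distance between two points
#'
#' Spherical law of cosines with the argument of `acos` clamped to
#' \[-1, 1\] so antipodal or coincident points never raise domain errors.
#'
#' @param a,b numeric length-2 vectors `c(lat, lon)` in degrees.
#' @param radius_km sphere radius; default 6371 km (mean Earth radius).
#' @return Distance in kilometres.
#' @export
great_circle_km <- function(a, b, radius_km = 6371) {
  to_rad <- pi / 180
  la <- a[1] * to_rad; lb <- b[1] * to_rad
  dlon <- (a[2] - b[2]) * to_rad
  cosang <- sin(la) * sin(lb) + cos(la) * cos(lb) * cos(dlon)
  radius_km * acos(pmin(1, pmax(-1, cosang)))
}

# full pairwise great-circle distance matrix for a county_geo table
.distance_matrix <- function(geo, radius_km = 6371) {
  to_rad <- pi / 180
  lat <- geo$lat * to_rad
  lon <- geo$lon * to_rad
  cosang <- outer(sin(lat), sin(lat)) +
    outer(cos(lat), cos(lat)) * cos(outer(lon, lon, "-"))
  d <- radius_km * acos(pmin(pmax(cosang, -1), 1))
  diag(d) <- 0
  dimnames(d) <- list(geo$fips, geo$fips)
  d
}

#' Nearest-neighbor county sets
#'
#' For every county, the `k` nearest other counties by great-circle
#' distance. Exactly `k` neighbors are kept; ties at the k-th distance are
#' broken by ascending FIPS for determinism.
#'
#' @param geo a `county_geo` table with at least `k + 1` counties.
#' @param k neighborhood size.
#' @return Object of class `neighbor_index`: a list with `neighbors`
#'   (list of FIPS vectors, sorted by distance), `dk` (distance to the
#'   k-th neighbor, km) and `k`.
#' @export
knn_sets <- function(geo, k) {
  n <- nrow(geo)
  if (k < 1) stop("k must be positive")
  if (n < k + 1)
    stop("need at least k + 1 = ", k + 1, " counties, got ", n)
  d <- .distance_matrix(geo)
  neighbors <- vector("list", n)
  dk <- numeric(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(d[i, others], geo$fips[others])]
    sel <- ord[seq_len(k)]
    neighbors[[i]] <- geo$fips[sel]
    dk[i] <- d[i, sel[k]]
  }
  structure(list(neighbors = stats::setNames(neighbors, geo$fips),
                 dk = stats::setNames(dk, geo$fips), k = k),
            class = "neighbor_index")
}

#' Local odds-ratio of a county's opioid reports to its neighbors'
#'
#' Ratio of the county's opioid reports summed over the year window to the
#' same sum over its k nearest neighboring counties. A county with no
#' opioid reports scores 0; a positive numerator over a zero denominator
#' is capped at `cap` with a warning.
#'
#' @inheritParams rho_yearly
#' @param neighbors a `neighbor_index` from [knn_sets()].
#' @param years year window for the sums.
#' @param cap ceiling for the zero-denominator case.
#' @return Non-negative ratio.
#' @export
lofc <- function(panel, neighbors, county, years, opioid_set, cap = 1e6) {
  county <- pad_fips(county)
  nb <- neighbors$neighbors[[county]]
  if (is.null(nb)) stop("county ", county, " absent from neighbor index")
  have <- unique(panel$tdrc$fips)
  missing_nb <- setdiff(nb, have)
  if (length(missing_nb) > 0)
    stop("neighbor county absent from panel: ", missing_nb[1])
  num <- sum(.opioid_yearly(panel, county, years, opioid_set))
  den <- sum(vapply(nb, function(j)
    sum(.opioid_yearly(panel, j, years, opioid_set)), numeric(1)))
  if (num == 0) return(0)
  if (den == 0) {
    warning("no opioid reports among neighbors of ", county,
            "; LOFC capped at ", cap)
    return(cap)
  }
  num / den
}

#' Compute the four severity indicators for every county
#'
#' One row per county with the mean opioid share (`rho`), the change rate
#' of opioid counts (`q`), the change rate of the opioid share (`Q`) and
#' the neighbor odds-ratio (`lofc`).
#'
#' @param panel a `drug_panel`.
#' @param geo a `county_geo` covering every county in the panel.
#' @param opioid_set substance names counted as opioids.
#' @param years_mean window for the mean share and the LOFC sums.
#' @param early,late windows for the change rates.
#' @param k neighborhood size.
#' @return data.frame of class `indicator_table` with columns `fips`,
#'   `rho`, `q`, `Q`, `lofc`; attribute `k_used` records `k`.
#' @export
compute_indicators <- function(panel, geo, opioid_set,
                               years_mean = 2010:2017,
                               early = 2010:2013, late = 2014:2017,
                               k = 5) {
  counties <- sort(unique(panel$tdrc$fips))
  missing_geo <- setdiff(counties, geo$fips)
  if (length(missing_geo) > 0)
    stop("county missing from coordinate table: ", missing_geo[1])
  nb <- knn_sets(geo[geo$fips %in% counties, , drop = FALSE], k)
  out <- data.frame(
    fips = counties,
    rho = vapply(counties, function(i)
      rho_mean(panel, i, years_mean, opioid_set), numeric(1)),
    q = vapply(counties, function(i)
      q_rate(panel, i, early, late, opioid_set), numeric(1)),
    Q = vapply(counties, function(i)
      Q_rate(panel, i, early, late, opioid_set), numeric(1)),
    lofc = vapply(counties, function(i)
      lofc(panel, nb, i, years_mean, opioid_set), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, k_used = k, class = c("indicator_table", "data.frame"))
}
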