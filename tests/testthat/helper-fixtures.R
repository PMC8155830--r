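# Shared fixtures and independent oracles used across the test files.

# Build a small drug panel from opioid/other count matrices
# (counties x years). One opioid substance ("heroin") and one other
# ("cocaine"); county total = opioid + other.
toy_panel <- function(opioid, other, years,
                      fips = sprintf("%05d", seq_len(nrow(opioid))),
                      state = "VA") {
  nc <- nrow(opioid)
  stopifnot(ncol(opioid) == length(years), dim(opioid) == dim(other))
  recs <- do.call(rbind, lapply(seq_len(nc), function(i) {
    data.frame(fips = fips[i], state = state, county = paste0("C", i),
               year = rep(years, 2),
               substance = rep(c("heroin", "cocaine"), each = length(years)),
               dr = c(opioid[i, ], other[i, ]), stringsAsFactors = FALSE)
  }))
  tdrc <- do.call(rbind, lapply(seq_len(nc), function(i) {
    data.frame(fips = fips[i], year = years,
               tdrc = opioid[i, ] + other[i, ], stringsAsFactors = FALSE)
  }))
  tdrs <- stats::aggregate(tdrc$tdrc, by = list(year = tdrc$year), FUN = sum)
  tdrs <- data.frame(state = state, year = tdrs$year, tdrs = tdrs$x,
                     stringsAsFactors = FALSE)
  drug_panel(recs, tdrc, tdrs)
}

# Independent straight-line evaluation of the entropy-weight / rank-sum
# steps: explicit per-element loops, benefit direction only.
ewm_oracle <- function(x) {
  n <- nrow(x); m <- ncol(x)
  e <- numeric(m)
  for (j in seq_len(m)) {
    xt <- x[, j] - min(x[, j])
    p <- xt / sum(xt)
    s <- 0
    for (i in seq_len(n)) if (p[i] > 0) s <- s + p[i] * log(p[i])
    e[j] <- -s / log(n)
  }
  h <- (1 - e) / sum(1 - e)
  R <- matrix(0, n, m)
  for (j in seq_len(m)) R[, j] <- rank(x[, j], ties.method = "average")
  rsr <- numeric(n)
  for (i in seq_len(n)) rsr[i] <- sum(h * R[i, ]) / n
  list(e = e, h = h, rsr = rsr)
}

# Haversine great-circle distance (independent of the law-of-cosines
# implementation), km.
haversine_km <- function(a, b, radius_km = 6371) {
  to_rad <- pi / 180
  dlat <- (b[1] - a[1]) * to_rad
  dlon <- (b[2] - a[2]) * to_rad
  h <- sin(dlat / 2)^2 +
    cos(a[1] * to_rad) * cos(b[1] * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(min(1, sqrt(h)))
}

# Simulate a stationary AR(p) series with standard-normal-scaled noise.
simulate_ar <- function(phi, n, sd, burn = 50) {
  p <- length(phi)
  x <- numeric(n + burn + p)
  for (t in (p + 1):length(x))
    x[t] <- sum(phi * x[t - seq_len(p)]) + rnorm(1, 0, sd)
  x[(burn + p + 1):length(x)]
}

# Small synthetic dataset reused by several files (kept small for speed).
small_dataset <- function(seed = 11, n = 30) {
  generate_dataset(synthetic_config(n_counties = n, seed = seed))
}
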