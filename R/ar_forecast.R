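#' Fit an autoregressive model by conditional least squares
#'
#' Estimates x_t = phi_1 x_{t-1} + ... + phi_p x_{t-p} + e by regressing
#' each value on its p predecessors. The model has no intercept by
#' default; `demean = TRUE` subtracts the series mean before fitting and
#' adds it back in forecasts, which is usually more plausible for count
#' series.
#'
#' @param series numeric vector, ordered in time.
#' @param p model order (>= 1).
#' @param demean subtract the series mean before fitting.
#' @return Object of class `ar_fit`: coefficients `phi`, order `p`,
#'   residual variance `sigma2`, the training length and the mean used.
#' @export
fit_ar <- function(series, p = 2, demean = FALSE) {
  series <- as.numeric(series)
  n <- length(series)
  if (p < 1) stop("order p must be >= 1")
  if (n < p + 2) stop("series too short for order ", p,
                      ": need at least ", p + 2, " points")
  if (any(!is.finite(series))) stop("series contains non-finite values")
  mu <- if (demean) mean(series) else 0
  x <- series - mu
  emb <- stats::embed(x, p + 1)   # col 1 = x_t, cols 2..p+1 = lags 1..p
  y <- emb[, 1]
  X <- emb[, -1, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("singular lag design: series has no usable variation")
  phi <- as.numeric(qr.coef(qrX, y))
  resid <- y - X %*% phi
  structure(list(phi = phi, p = p, sigma2 = sum(resid^2) / length(y),
                 n = n, mean = mu, demean = demean),
            class = "ar_fit")
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("AR(%d) fit (conditional least squares, %s), n = %d\n",
              x$p, if (x$demean) "mean-centered" else "no intercept", x$n))
  cat("phi:", paste(sprintf("%.4f", x$phi), collapse = ", "),
      sprintf("  sigma^2 = %.4g\n", x$sigma2))
  invisible(x)
}

#' Select an AR order by AIC
#'
#' Fits conditional-least-squares AR models over a range of orders and
#' returns the order minimizing the Gaussian AIC computed on the common
#' effective sample (the observations usable at the largest order), so
#' likelihoods are comparable.
#'
#' @param series numeric vector.
#' @param orders candidate orders (default 1:4).
#' @param demean passed to [fit_ar()].
#' @return The selected order (integer).
#' @export
select_ar_order <- function(series, orders = 1:4, demean = FALSE) {
  series <- as.numeric(series)
  pmax_ <- max(orders)
  if (length(series) < pmax_ + 2)
    orders <- orders[orders <= length(series) - 2]
  if (length(orders) == 0) stop("series too short for any candidate order")
  pmax_ <- max(orders)
  mu <- if (demean) mean(series) else 0
  x <- series - mu
  emb <- stats::embed(x, pmax_ + 1)
  y <- emb[, 1]
  aic <- vapply(orders, function(p) {
    X <- emb[, 1 + seq_len(p), drop = FALSE]
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    length(y) * log(rss / length(y)) + 2 * p
  }, numeric(1))
  orders[which.min(aic)]
}

#' Iterated AR forecasts
#'
#' One-step predictions fed back as lags for `horizon` steps. Forecasts of
#' count series are clipped at zero when `clip_zero = TRUE`.
#'
#' @param fit an `ar_fit`.
#' @param series the observed series the forecast continues.
#' @param horizon number of steps ahead (>= 1).
#' @param clip_zero floor forecasts at 0.
#' @return Numeric vector of length `horizon`.
#' @export
forecast_ar <- function(fit, series, horizon, clip_zero = TRUE) {
  if (horizon < 1) stop("horizon must be >= 1")
  x <- as.numeric(series) - fit$mean
  out <- numeric(horizon)
  for (h in seq_len(horizon)) {
    lags <- x[length(x) - seq_len(fit$p) + 1]
    pred <- sum(fit$phi * lags) + fit$mean
    if (clip_zero) pred <- max(pred, 0)
    out[h] <- pred
    x <- c(x, pred - fit$mean)
  }
  out
}

# per-county yearly series of total and opioid drug reports
.county_series <- function(panel, county, years, opioid_set) {
  county <- pad_fips(county)
  td <- panel$tdrc[panel$tdrc$fips == county, , drop = FALSE]
  tot <- stats::setNames(rep(NA_real_, length(years)), years)
  tot[as.character(td$year)] <- td$tdrc
  list(total = tot,
       opioid = .opioid_yearly(panel, county, years, opioid_set))
}

#' Forecast county severity through a frozen evaluation model
#'
#' For every county, total and opioid drug-report series are extended
#' `horizon` years ahead with AR(p) models (all counties forecast jointly,
#' so LOFC sums over forecast years use the neighbors' forecasts too). The
#' four indicators are recomputed over the windows shifted by the horizon
#' and each county is re-scored with [score_new_object()] against the
#' frozen model; level changes are reported as
#' current level - forecast level (positive = worsening).
#'
#' @param panel historical `drug_panel`.
#' @param geo `county_geo` table.
#' @param state frozen `ewm_rsr` fit on the historical indicators.
#' @param opioid_set substance names counted as opioids.
#' @param years_mean,early,late historical indicator windows (shifted by
#'   `horizon` for the forecast indicators).
#' @param k neighborhood size.
#' @param p AR order (forecasts fall back to the last observed value for
#'   counties whose series are too short or degenerate; these are flagged).
#' @param horizon years ahead (default 4). `horizon = 0` returns the
#'   current scores unchanged.
#' @return data.frame of class `severity_forecast`: per county the current
#'   and forecast corrected RSR and level, the level change `delta_level`,
#'   forecast indicator values and a `fallback` flag.
#' @export
forecast_severity <- function(panel, geo, state, opioid_set,
                              years_mean = 2010:2017,
                              early = 2010:2013, late = 2014:2017,
                              k = 5, p = 2, horizon = 4) {
  counties <- sort(unique(panel$tdrc$fips))
  cur <- state$result[match(counties, state$result$id), ]
  if (horizon == 0) {
    out <- data.frame(fips = counties,
                      rsr_current = cur$corrected_rsr,
                      rsr_forecast = cur$corrected_rsr,
                      level_current = cur$level,
                      level_forecast = cur$level,
                      delta_level = 0L, fallback = FALSE,
                      stringsAsFactors = FALSE)
    class(out) <- c("severity_forecast", "data.frame")
    return(out)
  }
  years <- sort(unique(panel$tdrc$year))
  fyears <- (max(years) + 1):(max(years) + horizon)
  fallback <- logical(length(counties))
  # build an extended panel of aggregate opioid / total counts
  ext_tdrc <- NULL
  ext_rec <- NULL
  for (ci in seq_along(counties)) {
    co <- counties[ci]
    s <- .county_series(panel, co, years, opioid_set)
    fc <- function(v) {
      ok <- all(is.finite(v)) && length(v) >= p + 2 && stats::sd(v) > 0
      if (!ok) return(NULL)
      f <- tryCatch(fit_ar(v, p), error = function(e) NULL)
      if (is.null(f)) return(NULL)
      forecast_ar(f, v, horizon)
    }
    ftot <- fc(s$total)
    fop <- fc(s$opioid)
    if (is.null(ftot)) { ftot <- rep(s$total[length(s$total)], horizon)
                         fallback[ci] <- TRUE }
    if (is.null(fop)) { fop <- rep(s$opioid[length(s$opioid)], horizon)
                        fallback[ci] <- TRUE }
    fop <- pmin(fop, ftot)  # opioid reports cannot exceed all drug reports
    ext_tdrc <- rbind(ext_tdrc, data.frame(
      fips = co, year = fyears, tdrc = ftot, stringsAsFactors = FALSE))
    ext_rec <- rbind(ext_rec, data.frame(
      fips = co, state = "NA", county = co, year = fyears,
      substance = "opioid_forecast", dr = fop, stringsAsFactors = FALSE))
  }
  if (any(fallback))
    warning(sum(fallback), " county series too short or degenerate for ",
            "AR(", p, "); last observed value carried forward")
  ext <- structure(list(
    records = rbind(panel$records[, c("fips", "state", "county", "year",
                                      "substance", "dr")], ext_rec),
    tdrc = rbind(panel$tdrc, ext_tdrc),
    tdrs = panel$tdrs), class = "drug_panel")
  f_opioids <- c(opioid_set, "opioid_forecast")
  ind_f <- compute_indicators(ext, geo, f_opioids,
                              years_mean = years_mean + horizon,
                              early = early + horizon,
                              late = late + horizon, k = k)
  scored <- score_new_object(state,
                             as.matrix(ind_f[, c("rho", "q", "Q", "lofc")]))
  out <- data.frame(fips = counties,
                    rsr_current = cur$corrected_rsr,
                    rsr_forecast = scored$corrected_rsr,
                    level_current = cur$level,
                    level_forecast = scored$level,
                    delta_level = cur$level - scored$level,
                    rho_forecast = ind_f$rho, q_forecast = ind_f$q,
                    Q_forecast = ind_f$Q, lofc_forecast = ind_f$lofc,
                    fallback = fallback,
                    stringsAsFactors = FALSE)
  class(out) <- c("severity_forecast", "data.frame")
  out
}
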