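#' Rank an indicator matrix
#'
#' Benefit indicators are ranked ascending (the largest value receives
#' rank n), cost indicators descending; exact ties receive the mean of the
#' ranks they span, so every column's ranks sum to n(n+1)/2.
#'
#' @param values numeric matrix, objects (rows) x indicators (columns).
#' @param directions character vector (`"benefit"` or `"cost"`) per
#'   column; recycled if length 1.
#' @return Matrix of ranks with the same dimnames as `values`.
#' @export
rank_indicators <- function(values, directions = "benefit") {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need at least 2 objects to rank")
  directions <- rep_len(directions, ncol(values))
  if (!all(directions %in% c("benefit", "cost")))
    stop("directions must be 'benefit' or 'cost'")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite indicator value at object ", bad[1],
         ", indicator ", bad[2])
  }
  R <- values
  for (j in seq_len(ncol(values))) {
    x <- if (directions[j] == "cost") -values[, j] else values[, j]
    R[, j] <- rank(x, ties.method = "average")
  }
  R
}

#' Entropy weights for a set of indicators
#'
#' Each column is shifted to be non-negative by subtracting its minimum,
#' normalized to shares, and its Shannon entropy computed with the
#' convention 0 * log 0 = 0. The weight of an indicator is proportional to
#' one minus its entropy, so more dispersed indicators carry more weight.
#' A constant column carries no information: its shares are taken as
#' uniform, giving entropy 1 and weight 0.
#'
#' @param values numeric matrix, objects (rows) x indicators (columns).
#' @return List with `entropy` (per indicator, in \[0, 1\]) and `weights`
#'   (non-negative, summing to 1).
#' @export
entropy_weights <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 2) stop("need at least 2 objects")
  e <- numeric(ncol(values))
  for (j in seq_len(ncol(values))) {
    x <- values[, j] - min(values[, j])
    s <- sum(x)
    p <- if (s == 0) rep(1 / n, n) else x / s
    plogp <- ifelse(p > 0, p * log(p), 0)
    e[j] <- -sum(plogp) / log(n)
  }
  d <- 1 - e
  if (sum(d) <= 0)
    stop("all indicator columns are constant: no information to weight")
  w <- d / sum(d)
  names(e) <- names(w) <- colnames(values)
  list(entropy = e, weights = w)
}

#' Weighted rank-sum ratio
#'
#' The composite score of each object: the weighted mean of its
#' per-indicator ranks divided by the number of objects,
#' RSR_i = (1/n) * sum_j h_j R_ij, always in \[1/n, 1\].
#'
#' @param ranks rank matrix from [rank_indicators()].
#' @param weights non-negative indicator weights summing to 1.
#' @return Numeric vector of raw RSR values.
#' @export
rank_sum_ratio <- function(ranks, weights) {
  ranks <- as.matrix(ranks)
  if (length(weights) != ncol(ranks))
    stop("weights length does not match number of indicators")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  as.numeric(ranks %*% weights) / nrow(ranks)
}

#' Probit frequency correction of raw RSR values
#'
#' Objects sharing a raw RSR value form a group. Each group's cumulative
#' frequency is its mean rank divided by n; the last group's is corrected
#' to 1 - 1/(4n) so its probit is finite. Probit = standard-normal
#' quantile of the cumulative frequency plus 5. A least-squares line
#' RSR = a + b * Probit is fitted over the groups and its fitted values
#' are the corrected RSR scores.
#'
#' @param raw_rsr numeric vector of raw RSR values (one per object).
#' @return List with per-object vectors `raw_rsr`, `probit`,
#'   `corrected_rsr`; the group table `groups` (columns `rsr`, `freq`,
#'   `mean_rank`, `cum_freq`, `probit`, `corrected`); and the regression
#'   `a`, `b`, `r_squared`.
#' @export
probit_correction <- function(raw_rsr) {
  n <- length(raw_rsr)
  rk <- rank(raw_rsr, ties.method = "average")
  grp_vals <- sort(unique(raw_rsr))
  if (length(grp_vals) < 2)
    stop("all objects share one RSR value: probit regression undefined")
  gi <- match(raw_rsr, grp_vals)
  freq <- as.integer(table(gi))
  mean_rank <- as.numeric(tapply(rk, gi, mean))
  cum_freq <- mean_rank / n
  cum_freq[length(cum_freq)] <- 1 - 1 / (4 * n)
  probit <- stats::qnorm(cum_freq) + 5
  fit <- stats::lm.fit(cbind(1, probit), grp_vals)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  fitted <- a + b * probit
  ss_res <- sum((grp_vals - fitted)^2)
  ss_tot <- sum((grp_vals - mean(grp_vals))^2)
  groups <- data.frame(rsr = grp_vals, freq = freq, mean_rank = mean_rank,
                       cum_freq = cum_freq, probit = probit,
                       corrected = fitted)
  list(raw_rsr = raw_rsr, probit = probit[gi], corrected_rsr = fitted[gi],
       groups = groups, a = unname(a), b = unname(b),
       r_squared = 1 - ss_res / ss_tot)
}

#' Default probit cut points for severity levels
#'
#' Equal-probability bands of the standard normal on the probit scale:
#' the quantiles at i/L for i = 1..L-1, shifted by 5.
#'
#' @param n_levels number of ordinal levels.
#' @return Increasing numeric vector of length `n_levels - 1`.
#' @export
default_level_boundaries <- function(n_levels = 6) {
  stats::qnorm(seq_len(n_levels - 1) / n_levels) + 5
}

#' Classify objects into ordinal severity levels
#'
#' Objects are binned by their probit value into `n_levels` ordered bands;
#' level 1 is the most severe (highest corrected RSR / probit) band.
#'
#' @param probit per-object probit values.
#' @param n_levels number of levels (default 6).
#' @param boundaries optional explicit, strictly increasing probit cut
#'   points of length `n_levels - 1`; defaults to
#'   [default_level_boundaries()].
#' @return Integer vector of levels in `1:n_levels`.
#' @export
classify_levels <- function(probit, n_levels = 6, boundaries = NULL) {
  if (is.null(boundaries)) boundaries <- default_level_boundaries(n_levels)
  if (length(boundaries) != n_levels - 1)
    stop("need ", n_levels - 1, " boundaries for ", n_levels, " levels")
  if (any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing")
  n_levels - findInterval(probit, boundaries)
}

#' Fit the full entropy-weight rank-sum-ratio evaluation model
#'
#' Ranks the indicator table, computes entropy weights on the raw values,
#' forms weighted rank-sum ratios, applies the probit frequency correction
#' and regression, and assigns severity levels. The returned object freezes
#' everything needed to score new observations ([score_new_object()]).
#'
#' @param indicators an `indicator_table` (or any data.frame with a `fips`
#'   id column and numeric indicator columns), or a plain numeric matrix.
#' @param directions per-indicator `"benefit"`/`"cost"` flags; all four
#'   severity indicators are benefit-type (higher = more severe).
#' @param n_levels,boundaries level classification, see
#'   [classify_levels()].
#' @return Object of class `ewm_rsr`: the frozen reference values, weights,
#'   probit regression and per-object results (`$result` data.frame with
#'   columns `id`, `raw_rsr`, `probit`, `corrected_rsr`, `level`).
#' @export
ewm_rsr_fit <- function(indicators, directions = "benefit",
                        n_levels = 6, boundaries = NULL) {
  if (is.data.frame(indicators)) {
    idcol <- intersect(c("fips", "id"), names(indicators))[1]
    ids <- if (!is.na(idcol)) indicators[[idcol]] else
      as.character(seq_len(nrow(indicators)))
    values <- as.matrix(indicators[, setdiff(names(indicators),
                                             c("fips", "id")), drop = FALSE])
  } else {
    values <- as.matrix(indicators)
    ids <- if (!is.null(rownames(values))) rownames(values) else
      as.character(seq_len(nrow(values)))
  }
  directions <- rep_len(directions, ncol(values))
  ranks <- rank_indicators(values, directions)
  ew <- entropy_weights(values)
  raw <- rank_sum_ratio(ranks, ew$weights)
  pc <- probit_correction(raw)
  lev <- classify_levels(pc$probit, n_levels, boundaries)
  result <- data.frame(id = ids, raw_rsr = raw, probit = pc$probit,
                       corrected_rsr = pc$corrected_rsr, level = lev,
                       stringsAsFactors = FALSE)
  structure(list(values = values, ids = ids, directions = directions,
                 entropy = ew$entropy, weights = ew$weights,
                 ranks = ranks, groups = pc$groups,
                 a = pc$a, b = pc$b, r_squared = pc$r_squared,
                 n_levels = n_levels,
                 boundaries = if (is.null(boundaries))
                   default_level_boundaries(n_levels) else boundaries,
                 result = result),
            class = "ewm_rsr")
}

#' @export
print.ewm_rsr <- function(x, ...) {
  cat("EWM-RSR evaluation of", nrow(x$values), "objects on",
      ncol(x$values), "indicators\n")
  cat("entropy weights:\n")
  print(round(x$weights, 4))
  cat(sprintf("probit regression: RSR = %.5f + %.5f * Probit (R^2 = %.4f)\n",
              x$a, x$b, x$r_squared))
  cat("severity levels:", paste(names(table(x$result$level)),
                                table(x$result$level),
                                sep = ":", collapse = " "), "\n")
  invisible(x)
}

# interpolated fractional rank of a new value within a reference column;
# cost columns are handled by negation; result clamped to [1, n]
.insert_rank <- function(ref, new_value, direction) {
  if (direction == "cost") { ref <- -ref; new_value <- -new_value }
  rk <- rank(ref, ties.method = "average")
  u <- sort(unique(ref))
  ur <- as.numeric(tapply(rk, match(ref, u), mean))
  if (length(u) == 1) {
    # constant reference column (zero entropy weight): tie unless the new
    # value strictly exceeds or undercuts the common value
    if (new_value > u) return(length(ref))
    if (new_value < u) return(1)
    return(ur[1])
  }
  r <- stats::approx(u, ur, xout = new_value, rule = 2)$y
  if (length(u) > 1) {
    if (new_value > u[length(u)]) r <- ur[length(ur)]
    if (new_value < u[1]) r <- ur[1]
  }
  min(max(r, 1), length(ref))
}

# piecewise-linear map from raw RSR to probit over the fitted groups,
# linearly extrapolated beyond the group range with the end segments
.rsr_to_probit <- function(groups, raw) {
  x <- groups$rsr; y <- groups$probit
  m <- length(x)
  vapply(raw, function(v) {
    if (v <= x[1]) {
      y[1] + (v - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
    } else if (v >= x[m]) {
      y[m] + (v - x[m]) * (y[m] - y[m - 1]) / (x[m] - x[m - 1])
    } else {
      stats::approx(x, y, xout = v)$y
    }
  }, numeric(1))
}

#' Score new observations against a frozen evaluation model
#'
#' Inserts each new object's indicator values into the reference ranking
#' (fractional ranks by interpolation), computes its raw RSR with the
#' frozen entropy weights, maps it to a probit through the fitted group
#' frequency curve (extrapolated linearly beyond the reference range) and
#' through the frozen regression to a corrected RSR and severity level.
#' Reference objects' scores are unchanged.
#'
#' @param state an `ewm_rsr` fit.
#' @param new_values numeric vector (one object) or matrix (objects x
#'   indicators) with the same indicator count/order as the reference.
#' @return data.frame with columns `raw_rsr`, `probit`, `corrected_rsr`,
#'   `level`, one row per new object.
#' @export
score_new_object <- function(state, new_values) {
  if (is.null(dim(new_values))) new_values <- matrix(new_values, nrow = 1)
  new_values <- as.matrix(new_values)
  if (ncol(new_values) != ncol(state$values))
    stop("new object has ", ncol(new_values), " indicators, reference has ",
         ncol(state$values))
  n <- nrow(state$values)
  raw <- apply(new_values, 1, function(v) {
    r <- vapply(seq_along(v), function(j)
      .insert_rank(state$values[, j], v[j], state$directions[j]), numeric(1))
    sum(state$weights * r) / n
  })
  probit <- .rsr_to_probit(state$groups, raw)
  corrected <- state$a + state$b * probit
  data.frame(raw_rsr = raw, probit = probit, corrected_rsr = corrected,
             level = classify_levels(probit, state$n_levels,
                                     state$boundaries))
}
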