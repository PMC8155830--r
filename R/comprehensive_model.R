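#' @useDynLib ewmrsr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Min-max normalize a design matrix
#'
#' Maps every column to \[0, 1\] by (x - min) / (max - min), storing the
#' column extrema so that new data can be mapped onto the same scale and
#' normalized values can be inverted. Constant columns are mapped to all
#' zeros with a warning.
#'
#' @param m numeric matrix (observations x variables) or vector.
#' @return Object of class `minmax`: list with `values`, `min`, `max`.
#' @export
minmax_normalize <- function(m) {
  v <- as.matrix(m)
  if (nrow(v) < 2) stop("need at least 2 rows to normalize")
  mins <- apply(v, 2, min)
  maxs <- apply(v, 2, max)
  rng <- maxs - mins
  const <- rng == 0
  if (any(const)) {
    warning("constant column(s) normalized to 0: ",
            paste(colnames(v)[const], collapse = ", "))
    rng[const] <- 1
  }
  out <- sweep(sweep(v, 2, mins), 2, rng, "/")
  out[, const] <- 0
  structure(list(values = out, min = mins, max = maxs), class = "minmax")
}

#' Map new data onto a stored min-max scale
#'
#' @param nd a `minmax` object.
#' @param newdata matrix with the same columns; values outside the stored
#'   range map linearly outside \[0, 1\].
#' @return Normalized matrix.
#' @export
apply_minmax <- function(nd, newdata) {
  v <- as.matrix(newdata)
  rng <- nd$max - nd$min
  rng[rng == 0] <- 1
  out <- sweep(sweep(v, 2, nd$min), 2, rng, "/")
  out[, nd$max == nd$min] <- 0
  out
}

#' Invert a min-max normalization
#'
#' @param nd a `minmax` object.
#' @param values normalized matrix.
#' @return Matrix on the original scale.
#' @export
invert_minmax <- function(nd, values) {
  rng <- nd$max - nd$min
  sweep(sweep(as.matrix(values), 2, rng, "*"), 2, nd$min, "+")
}

#' LASSO fit by cyclic coordinate descent
#'
#' Minimizes (1/n) sum_i (y_i - x_i' beta)^2 + lambda * ||beta||_1 over
#' beta. There is no intercept by default: with all variables min-max
#' normalized the regression function passes through the origin of the
#' normalized space; `intercept = TRUE` adds an unpenalized intercept.
#' Coordinates are updated by soft-thresholding until the largest
#' coefficient change falls below `tol`.
#'
#' @param x numeric design matrix (n x m), typically min-max normalized.
#' @param y numeric response of length n, typically min-max normalized.
#' @param lambda penalty (>= 0).
#' @param intercept include an unpenalized intercept.
#' @param tol convergence tolerance on coefficient changes.
#' @param max_iter iteration cap.
#' @param beta0 optional warm-start coefficient vector.
#' @return Object of class `lasso_fit`: `beta` (named), `intercept`,
#'   `lambda`, `objective`, `iterations`.
#' @export
lasso_fit <- function(x, y, lambda, intercept = FALSE, tol = 1e-8,
                      max_iter = 100000L, beta0 = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 2) stop("need at least 2 observations")
  if (length(y) != n) stop("response length does not match design")
  if (lambda < 0) stop("lambda must be >= 0")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in design or response")
  beta <- if (is.null(beta0)) numeric(m) else as.numeric(beta0)
  res <- .lasso_cd(x, as.numeric(y), lambda, intercept, tol,
                   as.integer(max_iter), beta)
  beta <- stats::setNames(as.numeric(res$beta), colnames(x))
  structure(list(beta = beta, intercept = res$intercept, lambda = lambda,
                 objective = res$rss / n + lambda * sum(abs(beta)),
                 iterations = res$iterations),
            class = "lasso_fit")
}

#' Predict from a LASSO fit
#'
#' @param object a `lasso_fit`.
#' @param newdata design matrix on the same (normalized) scale.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$beta) + object$intercept
}

#' Default penalty grid for LASSO path and cross-validation
#'
#' Log-spaced from the full-shrinkage threshold
#' lambda_max = 2 max_j |sum_i x_ij y_i| / n (above which all coefficients
#' are zero) down to `lambda_max * min_ratio`.
#'
#' @param x,y design and response.
#' @param nlambda grid size.
#' @param min_ratio smallest lambda as a fraction of `lambda_max`.
#' @return Decreasing numeric vector.
#' @export
lambda_grid <- function(x, y, nlambda = 50, min_ratio = 1e-4) {
  lam_max <- 2 * max(abs(crossprod(as.matrix(x), y))) / length(y)
  if (lam_max == 0) lam_max <- 1e-3
  exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = nlambda))
}

#' Select the LASSO penalty by leave-one-out cross-validation
#'
#' For each candidate lambda, fits n leave-one-out models and records the
#' mean squared prediction error. Two standard selections are reported:
#' the error-minimizing lambda (ties broken toward the larger, i.e.
#' sparser, lambda) and the one-standard-error lambda (the largest lambda
#' whose error is within one standard error of the minimum), which is the
#' usual choice for support recovery. `rule` picks which one the final
#' all-data refit uses.
#'
#' @param x,y normalized design and response.
#' @param grid penalty grid (decreasing); default [lambda_grid()].
#' @param intercept passed to [lasso_fit()].
#' @param rule `"min"` (default) or `"1se"`.
#' @return Object of class `lasso_cv`: selected `lambda`, final `fit`,
#'   `support` (nonzero coefficients of the final fit), `lambda_1se`,
#'   `support_1se`, and the `cv` data.frame (lambda, mse, se).
#' @export
loocv_select <- function(x, y, grid = NULL, intercept = FALSE,
                         rule = c("min", "1se")) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 observations for leave-one-out")
  if (is.null(grid)) grid <- lambda_grid(x, y)
  if (length(grid) == 0) stop("empty penalty grid")
  grid <- sort(grid, decreasing = TRUE)
  err <- .lasso_loocv_cpp(x, as.numeric(y), grid, intercept, 1e-8, 100000L)
  mse <- colMeans(err)
  se <- apply(err, 2, stats::sd) / sqrt(n)
  best <- which(mse <= min(mse) + 1e-15)[1]  # grid is decreasing: first = largest
  i1se <- which(mse <= mse[best] + se[best])[1]
  lam <- if (rule == "1se") grid[i1se] else grid[best]
  fit <- lasso_fit(x, y, lam, intercept = intercept)
  fit_1se <- if (i1se == best && rule == "min") fit else
    lasso_fit(x, y, grid[i1se], intercept = intercept)
  structure(list(lambda = lam, fit = fit,
                 support = names(fit$beta)[fit$beta != 0],
                 lambda_1se = grid[i1se],
                 support_1se = names(fit_1se$beta)[fit_1se$beta != 0],
                 rule = rule,
                 cv = data.frame(lambda = grid, mse = mse, se = se)),
            class = "lasso_cv")
}

#' @export
print.lasso_cv <- function(x, ...) {
  cat(sprintf("LOOCV-selected lambda = %.4g (mse = %.4g), %d nonzero of %d\n",
              x$lambda, min(x$cv$mse), length(x$support),
              length(x$fit$beta)))
  invisible(x)
}

#' Fit the per-indicator comprehensive LASSO models
#'
#' Min-max normalizes the census matrix and each indicator column, then
#' selects a LASSO model per indicator by leave-one-out cross-validation.
#'
#' @param census a `census_table` (imputed) or numeric matrix with FIPS
#'   rownames.
#' @param indicators an `indicator_table`.
#' @param grid optional shared penalty grid.
#' @return Object of class `comprehensive_fit`: `design` (the `minmax`
#'   of the census matrix), `y_norm` (per-indicator `minmax`), `fits`
#'   (per-indicator `lasso_cv`), and the county order `fips`.
#' @export
fit_comprehensive <- function(census, indicators, grid = NULL) {
  vals <- if (inherits(census, "census_table")) census$values else
    as.matrix(census)
  if (any(is.na(vals))) stop("census table has missing cells; impute first")
  fips <- indicators$fips
  miss <- setdiff(fips, rownames(vals))
  if (length(miss) > 0)
    stop("county missing from census table: ", miss[1])
  vals <- vals[fips, , drop = FALSE]
  design <- minmax_normalize(vals)
  ind_cols <- c("rho", "q", "Q", "lofc")
  y_norm <- list(); fits <- list()
  for (nm in ind_cols) {
    yn <- minmax_normalize(matrix(indicators[[nm]], ncol = 1,
                                  dimnames = list(NULL, nm)))
    y_norm[[nm]] <- yn
    fits[[nm]] <- loocv_select(design$values, as.numeric(yn$values),
                               grid = grid)
  }
  structure(list(design = design, y_norm = y_norm, fits = fits,
                 fips = fips), class = "comprehensive_fit")
}

# normalized-scale predictions for all indicators on a (normalized) design
.comp_predict <- function(cfit, xnorm) {
  sapply(names(cfit$fits), function(nm) predict(cfit$fits[[nm]]$fit, xnorm))
}

#' Comprehensive (demographically modified) indicators
#'
#' Each indicator is multiplied by its LASSO-predicted normalized value,
#' blending the county's historical severity with its demographic profile;
#' negative predictions are floored at 0 so the modified indicators stay
#' non-negative severity multiples.
#'
#' @param cfit a `comprehensive_fit`.
#' @param indicators the `indicator_table` the fit was built on.
#' @return `indicator_table` of modified values, with the prediction
#'   matrix attached as attribute `predictions`.
#' @export
modify_indicators <- function(cfit, indicators) {
  if (!identical(indicators$fips, cfit$fips))
    stop("indicator table does not match the fitted county set")
  pred <- .comp_predict(cfit, cfit$design$values)
  predf <- pmax(pred, 0)
  out <- indicators
  for (nm in colnames(pred)) out[[nm]] <- predf[, nm] * indicators[[nm]]
  attr(out, "predictions") <- pred
  out
}

#' One step of the policy effect equation
#'
#' Updates a comprehensive value by the alpha-blended relative change in
#' its demographic prediction:
#' value_new = (alpha * (pred_new - pred_old) + pred_old) / pred_old *
#' value_old. With `alpha = 0`, or when the prediction is unchanged, the
#' value is unchanged.
#'
#' @param pred_old,pred_new normalized demographic predictions before and
#'   after the policy; `pred_old` must be nonzero.
#' @param value_old current comprehensive value.
#' @param alpha per-period effect rate in \[0, 1\].
#' @return Updated value.
#' @export
policy_effect_step <- function(pred_old, pred_new, value_old, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (any(pred_old == 0)) stop("prediction before the policy is zero")
  (alpha * (pred_new - pred_old) + pred_old) / pred_old * value_old
}

#' Define a policy scenario
#'
#' @param target_codes census variable codes the policy reduces.
#' @param reduction fractional decrease in \[0, 1\] applied to the targets.
#' @param alpha per-period effect rate in \[0, 1\] (default 0.2).
#' @param periods number of periods simulated (>= 1).
#' @param aggregation `"state"` (mean of county indicators per state) or
#'   `"county"`.
#' @return List of class `policy_scenario`.
#' @export
policy_scenario <- function(target_codes, reduction, alpha = 0.2,
                            periods = 5, aggregation = "state") {
  if (reduction < 0 || reduction > 1) stop("reduction must be in [0, 1]")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (periods < 1) stop("periods must be >= 1")
  if (!aggregation %in% c("state", "county"))
    stop("aggregation must be 'state' or 'county'")
  structure(list(target_codes = target_codes, reduction = reduction,
                 alpha = alpha, periods = periods,
                 aggregation = aggregation), class = "policy_scenario")
}

#' Simulate a demographic-targeted policy
#'
#' Reduces the target census variables by the scenario fraction,
#' recomputes the per-indicator LASSO predictions on the frozen
#' normalization scale, and applies the policy effect equation for the
#' given number of periods (each period's output is the next period's
#' input). After every period the comprehensive indicators are aggregated
#' (state means over counties, or kept per county), scored against the
#' frozen evaluation model, and the mean corrected RSR recorded.
#'
#' @param scenario a `policy_scenario`.
#' @param cfit the baseline `comprehensive_fit`.
#' @param indicators the baseline `indicator_table`.
#' @param state an `ewm_rsr` fit on the baseline comprehensive indicators
#'   (see [modify_indicators()]).
#' @param census the (imputed) `census_table` used in the baseline fit.
#' @param groups named vector mapping county FIPS to aggregation group
#'   (e.g. state); required when `scenario$aggregation == "state"`.
#' @return data.frame of class `scenario_trajectory` with columns
#'   `period` (0 = baseline), `rsr` (mean corrected RSR over aggregation
#'   units) and `delta_rsr` (previous minus current); the per-unit scores
#'   are attached as attribute `units`.
#' @export
simulate_policy <- function(scenario, cfit, indicators, state, census,
                            groups = NULL) {
  vals <- if (inherits(census, "census_table")) census$values else
    as.matrix(census)
  vals <- vals[cfit$fips, , drop = FALSE]
  miss <- setdiff(scenario$target_codes, colnames(vals))
  if (length(miss) > 0)
    stop("target census code absent from design: ", miss[1])
  if (scenario$aggregation == "state") {
    if (is.null(groups)) stop("state aggregation requires a groups mapping")
    grp <- groups[cfit$fips]
    if (any(is.na(grp))) stop("groups mapping missing a county")
  } else grp <- cfit$fips

  pred_old <- .comp_predict(cfit, cfit$design$values)
  vals_new <- vals
  vals_new[, scenario$target_codes] <-
    vals_new[, scenario$target_codes] * (1 - scenario$reduction)
  pred_new <- .comp_predict(cfit, apply_minmax(cfit$design, vals_new))
  if (any(pred_old == 0))
    stop("baseline demographic prediction is zero for some county")

  comp <- modify_indicators(cfit, indicators)
  ind_cols <- c("rho", "q", "Q", "lofc")
  value <- as.matrix(comp[, ind_cols])

  agg_score <- function(v) {
    m <- apply(v, 2, function(col) tapply(col, grp, mean))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    score_new_object(state, m)$corrected_rsr
  }
  ratio <- (scenario$alpha * (pred_new - pred_old) + pred_old) / pred_old

  rsr <- numeric(scenario$periods + 1)
  units <- vector("list", scenario$periods + 1)
  units[[1]] <- agg_score(value)
  rsr[1] <- mean(units[[1]])
  for (p in seq_len(scenario$periods)) {
    value <- value * ratio
    units[[p + 1]] <- agg_score(value)
    rsr[p + 1] <- mean(units[[p + 1]])
  }
  out <- data.frame(period = 0:scenario$periods, rsr = rsr,
                    delta_rsr = c(NA, -diff(rsr)))
  attr(out, "units") <- do.call(rbind, units)
  class(out) <- c("scenario_trajectory", "data.frame")
  out
}
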