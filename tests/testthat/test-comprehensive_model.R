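test_that("min-max normalization maps to [0,1] and inverts", {
  nd <- minmax_normalize(cbind(a = c(1, 2, 3)))
  expect_equal(as.numeric(nd$values), c(0, 0.5, 1))
  expect_warning(ndc <- minmax_normalize(cbind(a = c(5, 5))), "constant")
  expect_equal(as.numeric(ndc$values), c(0, 0))
  set.seed(5)
  m <- matrix(rnorm(40, 50, 20), 10, 4, dimnames = list(NULL, letters[1:4]))
  nd <- minmax_normalize(m)
  expect_true(all(nd$values >= 0 & nd$values <= 1))
  expect_equal(invert_minmax(nd, nd$values), m, tolerance = 1e-12)
  # stored extrema reproduce the same mapping on new data
  expect_equal(apply_minmax(nd, m), unname(nd$values) + 0 * m,
               tolerance = 1e-12)
})

test_that("the penalized fit matches closed-form solutions", {
  set.seed(10)
  X <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(X %*% c(1, -0.5, 0.2)) + rnorm(20, 0, 0.05)
  # lambda = 0 is ordinary least squares (no intercept)
  f0 <- lasso_fit(X, y, 0)
  ols <- qr.coef(qr(X), y)
  expect_equal(unname(f0$beta), unname(ols), tolerance = 1e-6)
  # full-shrinkage threshold zeroes every coefficient
  lam_max <- 2 * max(abs(crossprod(X, y))) / length(y)
  expect_equal(unname(lasso_fit(X, y, lam_max)$beta), c(0, 0, 0))
  expect_gt(max(abs(lasso_fit(X, y, lam_max * 0.99)$beta)), 0)
  # univariate soft-threshold closed form
  x1 <- X[, 1, drop = FALSE]
  cc <- sum(x1 * y) / 20
  vv <- sum(x1^2) / 20
  for (lam in c(0.01, 0.05, 0.2)) {
    bhat <- sign(cc) * max(abs(cc) - lam / 2, 0) / vv
    expect_equal(unname(lasso_fit(x1, y, lam)$beta), bhat,
                 tolerance = 1e-10)
  }
  # objective never exceeds the zero or OLS objectives
  obj <- function(b, lam) mean((y - X %*% b)^2) + lam * sum(abs(b))
  for (lam in c(0.01, 0.1)) {
    f <- lasso_fit(X, y, lam)
    expect_lte(f$objective, obj(c(0, 0, 0), lam) + 1e-12)
    expect_lte(f$objective, obj(ols, lam) + 1e-12)
  }
})

test_that("the coefficient path shrinks monotonically in the penalty", {
  set.seed(20)
  X <- matrix(runif(200), 20, 10)
  y <- as.numeric(X %*% c(2, -1, rep(0, 8))) + rnorm(20, 0, 0.2)
  grid <- lambda_grid(X, y, nlambda = 20)
  l1 <- vapply(sort(grid), function(l) sum(abs(lasso_fit(X, y, l)$beta)),
               numeric(1))
  expect_true(all(diff(l1) <= 1e-8))
})

test_that("the fit agrees with glmnet on its own objective scaling", {
  skip_if_not_installed("glmnet")
  set.seed(30)
  X <- matrix(rnorm(300), 30, 10)
  y <- as.numeric(X %*% c(1, -1, 0.5, rep(0, 7))) + rnorm(30, 0, 0.1)
  # (1/n) RSS + lambda L1  ==  2 * [ (1/2n) RSS + (lambda/2) L1 ]
  for (lam in c(0.02, 0.1, 0.5)) {
    g <- glmnet::glmnet(X, y, lambda = lam / 2, intercept = FALSE,
                        standardize = FALSE, thresh = 1e-14)
    expect_equal(unname(lasso_fit(X, y, lam)$beta),
                 as.numeric(g$beta), tolerance = 1e-5)
  }
})

test_that("leave-one-out selection behaves at the grid edges", {
  set.seed(40)
  X <- matrix(runif(150), 30, 5)
  y <- as.numeric(X %*% c(1, 0.5, 0, 0, 0)) + rnorm(30, 0, 0.05)
  # a one-point grid selects that point
  sel1 <- loocv_select(X, y, grid = 0.01)
  expect_equal(sel1$lambda, 0.01)
  # pure-noise response selects a large penalty and a near-empty model
  yn <- rnorm(30, 0, 1)
  seln <- loocv_select(X, yn)
  g <- sort(lambda_grid(X, yn), decreasing = TRUE)
  expect_lte(which(g == seln$lambda), 10)  # among the largest grid values
  expect_lt(sum(abs(seln$fit$beta)), 0.3)
})

test_that("leave-one-out selection recovers a planted sparse support", {
  set.seed(1)
  X <- matrix(runif(1000), 100, 10, dimnames = list(NULL, paste0("V", 1:10)))
  y <- as.numeric(X %*% c(0.8, 0.6, 0.4, rep(0, 7))) + rnorm(100, 0, 0.05)
  sel <- loocv_select(X, y)
  truth <- c("V1", "V2", "V3")
  expect_true(all(truth %in% sel$support_1se))
  expect_lte(length(setdiff(sel$support_1se, truth)), 2)
})

test_that("comprehensive indicators compose prediction and history", {
  ds <- small_dataset(seed = 47, n = 30)
  cfit <- fit_comprehensive(impute_missing(ds$census), ds$indicators)
  comp <- modify_indicators(cfit, ds$indicators)
  # recompute the predictions by hand from the stored coefficients
  for (nm in c("rho", "q", "Q", "lofc")) {
    pred <- as.numeric(cfit$design$values %*% cfit$fits[[nm]]$fit$beta)
    expect_equal(comp[[nm]], pmax(pred, 0) * ds$indicators[[nm]],
                 tolerance = 1e-12)
  }
  # a unit prediction is the identity; a zero prediction annihilates
  expect_equal(policy_effect_step(0.5, 0.5, 3, 1), 3)
})

test_that("the policy effect equation has its limiting behaviors", {
  expect_equal(policy_effect_step(0.4, 0.2, 10, 0), 10)
  expect_equal(policy_effect_step(0.4, 0.4, 10, 1), 10)
  expect_equal(policy_effect_step(0.4, 0.2, 10, 1), 5)
  expect_error(policy_effect_step(0, 0.2, 10, 0.5), "zero")
  expect_error(policy_effect_step(0.4, 0.2, 10, 2), "alpha")
  # continuous and monotone in the new prediction
  vals <- vapply(seq(0.1, 0.8, by = 0.1), function(pn)
    policy_effect_step(0.4, pn, 10, 0.5), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("policy simulation is flat without a policy and responds with one", {
  ds <- small_dataset(seed = 53, n = 30)
  census <- impute_missing(ds$census)
  cfit <- fit_comprehensive(census, ds$indicators)
  comp <- modify_indicators(cfit, ds$indicators)
  ewm_c <- ewm_rsr_fit(comp)
  targets <- c("HC03_VC112", "HC03_VC114", "HC03_VC115")
  # zero reduction: trajectory equals baseline in every period
  tr0 <- simulate_policy(policy_scenario(targets, 0, periods = 3),
                         cfit, ds$indicators, ewm_c, census,
                         groups = ds$states)
  expect_equal(tr0$rsr, rep(tr0$rsr[1], 4))
  # alpha = 0: same
  tra <- simulate_policy(policy_scenario(targets, 0.5, alpha = 0,
                                         periods = 1),
                         cfit, ds$indicators, ewm_c, census,
                         groups = ds$states)
  expect_equal(tra$rsr[2], tra$rsr[1])
  expect_error(simulate_policy(policy_scenario("NOPE", 0.1), cfit,
                               ds$indicators, ewm_c, census,
                               groups = ds$states), "NOPE")
})
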