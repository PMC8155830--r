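test_that("ranking handles direction and ties", {
  x <- cbind(a = c(10, 20, 30))
  expect_equal(as.numeric(rank_indicators(x, "benefit")), c(1, 2, 3))
  expect_equal(as.numeric(rank_indicators(x, "cost")), c(3, 2, 1))
  xt <- cbind(a = c(10, 10, 30))
  expect_equal(as.numeric(rank_indicators(xt, "benefit")), c(1.5, 1.5, 3))
  # column rank sums are n(n+1)/2 even with ties
  set.seed(2)
  m <- matrix(sample(1:4, 40, replace = TRUE), 10, 4)
  expect_equal(unname(colSums(rank_indicators(m))), rep(55, 4))
  m[1, 1] <- NA
  expect_error(rank_indicators(m), "non-finite")
})

test_that("entropy weights follow the information-theoretic definition", {
  m <- cbind(a = c(1, 5, 9), b = c(1, 5, 9))
  ew <- entropy_weights(m)
  expect_equal(unname(ew$weights), c(0.5, 0.5))
  # p = (0, 1) has zero entropy by the 0*log(0) = 0 convention
  ew2 <- entropy_weights(cbind(a = c(0, 1), b = c(0.3, 0.7)))
  expect_equal(unname(ew2$entropy[1]), 0)
  # constant column carries no information
  ew3 <- entropy_weights(cbind(a = c(5, 5, 5), b = c(1, 2, 3)))
  expect_equal(unname(ew3$weights), c(0, 1))
  expect_error(entropy_weights(cbind(a = c(5, 5), b = c(2, 2))),
               "constant")
  # straight-line oracle on random matrices
  set.seed(7)
  for (r in 1:5) {
    m <- matrix(runif(20), 5, 4)
    ew <- entropy_weights(m)
    or <- ewm_oracle(m)
    expect_equal(unname(ew$entropy), or$e, tolerance = 1e-12)
    expect_equal(unname(ew$weights), or$h, tolerance = 1e-12)
    expect_equal(sum(ew$weights), 1, tolerance = 1e-12)
    expect_true(all(ew$weights >= 0))
  }
})

test_that("more dispersed share vectors never get smaller weights", {
  # mixing a column's shares toward uniform can only lower its weight
  set.seed(15)
  base <- c(0, 0.1, 0.2, 3, 8)
  for (lam in c(0.2, 0.5, 0.8)) {
    mixed <- (1 - lam) * base + lam * mean(base)
    ew <- entropy_weights(cbind(sharp = base, flat = mixed,
                                ref = c(1, 4, 2, 8, 5)))
    expect_gte(ew$weights["sharp"], ew$weights["flat"])
  }
})

test_that("rank-sum ratios have the defining scale and bounds", {
  x <- cbind(a = c(3, 1, 2))
  r <- rank_indicators(x)
  expect_equal(rank_sum_ratio(r, 1), c(3, 1, 2) / 3)
  # all-tied objects score (n+1)/(2n)
  xt <- cbind(a = rep(4, 5), b = rep(2, 5))
  rt <- rank_indicators(xt)
  expect_equal(rank_sum_ratio(rt, c(0.5, 0.5)), rep(6 / 10, 5))
  # hand computation on 4 x 2 with fixed weights
  m <- cbind(a = c(4, 2, 3, 1), b = c(10, 40, 20, 30))
  rr <- rank_indicators(m)
  w <- c(0.7, 0.3)
  expect_equal(rank_sum_ratio(rr, w),
               (0.7 * c(4, 2, 3, 1) + 0.3 * c(1, 4, 2, 3)) / 4)
  expect_error(rank_sum_ratio(rr, c(1)), "length")
  expect_error(rank_sum_ratio(rr, c(0.9, 0.3)), "sum to 1")
  # invariant to strictly monotone transforms of a column
  m2 <- m; m2[, 2] <- exp(m2[, 2] / 10)
  expect_equal(rank_sum_ratio(rank_indicators(m2), w),
               rank_sum_ratio(rr, w))
})

test_that("probit correction builds the frequency table as defined", {
  # four distinct values: cumulative frequencies 1/4, 2/4, 3/4, 1 - 1/(4n)
  pc <- probit_correction(c(0.2, 0.4, 0.6, 0.8))
  expect_equal(pc$groups$cum_freq, c(0.25, 0.5, 0.75, 1 - 1 / 16))
  # a cumulative frequency of one half maps to probit 5 exactly
  expect_equal(pc$groups$probit[2], 5)
  # n = 25 distinct values: last group's cumulative frequency is 0.99
  pc25 <- probit_correction(seq(0.1, 1, length.out = 25))
  expect_equal(pc25$groups$cum_freq[25], 0.99)
  # ties form one group with the mean rank
  pct <- probit_correction(c(0.3, 0.5, 0.5, 0.9))
  expect_equal(pct$groups$freq, c(1L, 2L, 1L))
  expect_equal(pct$groups$mean_rank, c(1, 2.5, 4))
  expect_error(probit_correction(rep(0.4, 6)), "one RSR value")
})

test_that("normal-quantile RSR values are reproduced by the regression", {
  n <- 40
  cf <- c(seq_len(n - 1) / n, 1 - 1 / (4 * n))
  raw <- 0.1 + 0.08 * (qnorm(cf) + 5)
  pc <- probit_correction(raw)
  expect_gt(pc$r_squared, 0.999)
  expect_lt(max(abs(pc$corrected_rsr - raw)), 1e-6)
  expect_equal(pc$a, 0.1, tolerance = 1e-9)
  expect_equal(pc$b, 0.08, tolerance = 1e-9)
  # corrected values increase with the probit
  ord <- order(pc$probit)
  expect_true(all(diff(pc$corrected_rsr[ord]) > 0))
})

test_that("level classification bins the probit scale from the top", {
  # explicit boundaries: probit 5.2 falls in band 3 of 6 from the top
  b <- c(3.5, 4.5, 5.0, 5.5, 6.5)
  expect_equal(classify_levels(5.2, 6, b), 3)
  expect_equal(classify_levels(c(7, 6.6), 6, b), c(1, 1))
  expect_equal(classify_levels(3.0, 6, b), 6)
  # levels are a non-increasing step function of the probit
  p <- seq(2, 8, by = 0.1)
  expect_true(all(diff(classify_levels(p)) <= 0))
  expect_error(classify_levels(5, 6, c(5, 4, 3, 2, 1)), "increasing")
  expect_error(classify_levels(5, 6, c(4, 5)), "boundaries")
})

test_that("new objects are scored consistently against the frozen model", {
  ds <- small_dataset(seed = 29, n = 25)
  fit <- ewm_rsr_fit(ds$indicators)
  vals <- fit$values
  # duplicating a reference object reproduces its corrected score
  for (i in c(1, 10, 25)) {
    sc <- score_new_object(fit, vals[i, ])
    expect_equal(sc$corrected_rsr, fit$result$corrected_rsr[i],
                 tolerance = 1e-9)
  }
  # a dominating object scores at least the reference maximum
  dom <- apply(vals, 2, max) * 1.1 + 0.1
  expect_gte(score_new_object(fit, dom)$corrected_rsr,
             max(fit$result$corrected_rsr))
  # the component-wise median lands mid-distribution
  med <- apply(vals, 2, stats::median)
  sc_med <- score_new_object(fit, med)$corrected_rsr
  qs <- stats::quantile(fit$result$corrected_rsr, c(0.25, 0.75))
  expect_gte(sc_med, qs[[1]])
  expect_lte(sc_med, qs[[2]])
  expect_error(score_new_object(fit, c(1, 2)), "indicators")
})

test_that("improving one benefit indicator never lowers the raw score", {
  ds <- small_dataset(seed = 37, n = 20)
  fit <- ewm_rsr_fit(ds$indicators)
  base <- fit$values[7, ]
  raw0 <- score_new_object(fit, base)$raw_rsr
  for (j in 1:4) {
    up <- base
    up[j] <- up[j] + abs(up[j]) + 1
    expect_gte(score_new_object(fit, up)$raw_rsr, raw0 - 1e-12)
  }
})

test_that("re-ranking by corrected RSR preserves the corrected order", {
  ds <- small_dataset(seed = 41, n = 20)
  fit <- ewm_rsr_fit(ds$indicators)
  ord1 <- order(fit$result$corrected_rsr)
  refit <- ewm_rsr_fit(matrix(fit$result$corrected_rsr, ncol = 1))
  ord2 <- order(refit$result$corrected_rsr)
  expect_equal(ord1, ord2)
})
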