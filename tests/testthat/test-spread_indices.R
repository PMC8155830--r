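test_that("yearly and mean opioid shares follow the defining ratios", {
  op <- matrix(c(30, 20, 0), 1); ot <- matrix(c(70, 30, 40), 1)
  p <- toy_panel(op, ot, 2010:2012)
  expect_equal(rho_yearly(p, "00001", 2010, "heroin"), 0.3)
  expect_equal(rho_yearly(p, "00001", 2011, "heroin"), 0.4)
  expect_equal(rho_yearly(p, "00001", 2012, "heroin"), 0)
  expect_equal(rho_mean(p, "00001", 2010:2011, "heroin"), 0.35)
  # substances not in the opioid set do not count
  expect_equal(rho_yearly(p, "00001", 2010, "oxycodone"), 0)
  expect_error(rho_yearly(p, "00001", 2015, "heroin"), "absent")
})

test_that("a county-year with no drug reports has share zero", {
  p <- toy_panel(matrix(c(0, 5), 1), matrix(c(0, 5), 1), 2010:2011)
  expect_equal(rho_yearly(p, "00001", 2010, "heroin"), 0)
})

test_that("count and share change rates divide by the mean-year gap", {
  op <- matrix(c(10, 10, 10, 10, 50, 50, 50, 50), 1)
  ot <- matrix(rep(50, 8), 1)
  p <- toy_panel(op, ot, 2010:2017)
  expect_equal(q_rate(p, "00001", 2010:2013, 2014:2017, "heroin"), 10)
  # two-year windows give a denominator of 2 (2012.5 - 2010.5)
  expect_equal(q_rate(p, "00001", 2010:2011, 2012:2013, "heroin"), 0)
  op2 <- matrix(c(10, 10, 30, 30, 0, 0, 0, 0), 1)
  p2 <- toy_panel(op2, ot, 2010:2017)
  expect_equal(q_rate(p2, "00001", 2010:2011, 2012:2013, "heroin"),
               (30 - 10) / 2)
  # constant series: both rates zero
  pc <- toy_panel(matrix(rep(10, 8), 1), matrix(rep(40, 8), 1), 2010:2017)
  expect_equal(q_rate(pc, "00001", 2010:2013, 2014:2017, "heroin"), 0)
  expect_equal(Q_rate(pc, "00001", 2010:2013, 2014:2017, "heroin"), 0)
  # share rising from 0.1 to 0.5 over the standard windows
  ps <- toy_panel(matrix(c(rep(10, 4), rep(50, 4)), 1),
                  matrix(c(rep(90, 4), rep(50, 4)), 1), 2010:2017)
  expect_equal(Q_rate(ps, "00001", 2010:2013, 2014:2017, "heroin"), 0.1)
  # declining share gives a negative rate
  pd <- toy_panel(matrix(c(rep(50, 4), rep(10, 4)), 1),
                  matrix(c(rep(50, 4), rep(90, 4)), 1), 2010:2017)
  expect_lt(Q_rate(pd, "00001", 2010:2013, 2014:2017, "heroin"), 0)
  expect_error(q_rate(p, "00001", 2010:2011, 2010:2011, "heroin"),
               "identical")
})

test_that("great-circle distances match the haversine oracle", {
  # the law of cosines loses precision near zero; sub-metre is enough
  expect_lt(great_circle_km(c(40, -80), c(40, -80)), 1e-3)
  expect_equal(great_circle_km(c(0, 0), c(0, 180)), pi * 6371,
               tolerance = 1e-9)
  set.seed(4)
  for (i in 1:200) {
    a <- c(runif(1, -89, 89), runif(1, -180, 180))
    b <- c(runif(1, -89, 89), runif(1, -180, 180))
    d1 <- great_circle_km(a, b)
    d2 <- haversine_km(a, b)
    expect_equal(d1, d2, tolerance = 1e-6 * max(d2, 1))
  }
})

test_that("distances are symmetric and satisfy the triangle inequality", {
  set.seed(8)
  pts <- cbind(runif(30, -60, 60), runif(30, -180, 180))
  for (r in 1:40) {
    ijk <- sample(30, 3)
    a <- pts[ijk[1], ]; b <- pts[ijk[2], ]; c_ <- pts[ijk[3], ]
    expect_equal(great_circle_km(a, b), great_circle_km(b, a),
                 tolerance = 1e-9)
    expect_lte(great_circle_km(a, c_),
               great_circle_km(a, b) + great_circle_km(b, c_) + 1e-9)
  }
})

test_that("k-nearest-neighbor sets match brute-force sorting", {
  # collinear equally spaced counties
  geo3 <- county_geo(c("00001", "00002", "00003"), c(30, 31, 32), c(0, 0, 0))
  nb <- knn_sets(geo3, 1)
  expect_equal(nb$neighbors[["00001"]], "00002")
  expect_equal(nb$neighbors[["00003"]], "00002")
  expect_true(nb$neighbors[["00002"]] %in% c("00001", "00003"))
  # k = n - 1 returns all other counties
  nb_all <- knn_sets(geo3, 2)
  expect_setequal(nb_all$neighbors[["00002"]], c("00001", "00003"))
  expect_error(knn_sets(geo3, 3), "at least")
  # brute-force oracle on 50 random counties
  set.seed(12)
  geo <- county_geo(sprintf("%05d", 1:50), runif(50, 35, 42),
                    runif(50, -85, -75))
  k <- 5
  nb <- knn_sets(geo, k)
  for (i in seq_len(50)) {
    d <- vapply(seq_len(50), function(j)
      great_circle_km(c(geo$lat[i], geo$lon[i]),
                      c(geo$lat[j], geo$lon[j])), numeric(1))
    ord <- setdiff(order(d, geo$fips), i)
    expect_equal(nb$neighbors[[geo$fips[i]]], geo$fips[ord[seq_len(k)]])
    expect_equal(nb$dk[[geo$fips[i]]], d[ord[k]])
  }
})

test_that("the neighbor odds-ratio equals the explicit double sum", {
  # county total 100 against 4 neighbors of 25 each
  op <- matrix(c(100, 25, 25, 25, 25), 5, 1)
  ot <- matrix(rep(10, 5), 5, 1)
  p <- toy_panel(op, ot, 2010)
  geo <- county_geo(sprintf("%05d", 1:5), c(40, 40.1, 39.9, 40, 40),
                    c(-80, -80, -80, -80.1, -79.9))
  nb <- knn_sets(geo, 4)
  expect_equal(lofc(p, nb, "00001", 2010, "heroin"), 1.0)
  # county with no opioid reports scores zero
  op0 <- op; op0[1, 1] <- 0
  p0 <- toy_panel(op0, ot, 2010)
  expect_equal(lofc(p0, nb, "00001", 2010, "heroin"), 0)
  # 5-county, 3-year layout against a hand enumeration with k = 2
  set.seed(3)
  opm <- matrix(rpois(15, 20), 5, 3)
  otm <- matrix(rpois(15, 30), 5, 3)
  pm <- toy_panel(opm, otm, 2010:2012)
  nb2 <- knn_sets(geo, 2)
  for (i in 1:5) {
    nbset <- match(nb2$neighbors[[sprintf("%05d", i)]],
                   sprintf("%05d", 1:5))
    num <- sum(opm[i, ])
    den <- 0
    for (j in nbset) for (t in 1:3) den <- den + opm[j, t]
    expect_identical(lofc(pm, nb2, sprintf("%05d", i), 2010:2012, "heroin"),
                     num / den)
  }
  # zero neighbor total with positive numerator is capped with a warning
  opz <- matrix(c(10, 0, 0, 0, 0), 5, 1)
  pz <- toy_panel(opz, ot, 2010)
  expect_warning(v <- lofc(pz, nb, "00001", 2010, "heroin"), "capped")
  expect_equal(v, 1e6)
})

test_that("indicator table is permutation-invariant and scale-equivariant", {
  ds <- small_dataset(seed = 19, n = 12)
  ind <- compute_indicators(ds$panel, ds$geo, c("heroin", "oxycodone",
                                                "fentanyl"))
  expect_true(all(ind$rho >= 0 & ind$rho <= 1))
  expect_true(all(ind$lofc >= 0))
  expect_true(all(is.finite(as.matrix(ind[, c("rho", "q", "Q", "lofc")]))))
  # permuting record order leaves values unchanged
  perm <- ds$panel
  set.seed(1)
  perm$records <- perm$records[sample(nrow(perm$records)), ]
  perm$tdrc <- perm$tdrc[sample(nrow(perm$tdrc)), ]
  ind_p <- compute_indicators(perm, ds$geo, c("heroin", "oxycodone",
                                              "fentanyl"))
  expect_equal(ind_p, ind)
  # doubling every count doubles q and leaves rho, Q, lofc unchanged
  dbl <- ds$panel
  dbl$records$dr <- dbl$records$dr * 2
  dbl$tdrc$tdrc <- dbl$tdrc$tdrc * 2
  dbl$tdrs$tdrs <- dbl$tdrs$tdrs * 2
  ind_d <- compute_indicators(dbl, ds$geo, c("heroin", "oxycodone",
                                             "fentanyl"))
  expect_equal(ind_d$rho, ind$rho, tolerance = 1e-12)
  expect_equal(ind_d$Q, ind$Q, tolerance = 1e-12)
  expect_equal(ind_d$lofc, ind$lofc, tolerance = 1e-12)
  expect_equal(ind_d$q, 2 * ind$q, tolerance = 1e-12)
})
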