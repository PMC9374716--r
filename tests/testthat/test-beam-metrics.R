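test_that("central-axis extraction averages the requested rings", {
  vals <- matrix(2.5, nrow = 6, ncol = 10)      # uniform field
  tg <- cylTallyGrid(vals)
  cur <- centralAxisCurve(tg, averagingRadius = 1.6)
  expect_equal(cur$value, rep(2.5, 10))
  # averaging radius spanning exactly one ring returns that ring
  vals2 <- matrix(seq_len(60), nrow = 6)
  tg2 <- cylTallyGrid(vals2)
  cur2 <- centralAxisCurve(tg2, averagingRadius = 0.5)
  expect_equal(cur2$value, as.numeric(vals2[1, ]))
  expect_error(centralAxisCurve(tg2, averagingRadius = -1), "> 0")
  expect_error(depthCurve(c(1, 1, 2), c(0, 0, 0)), "increasing")
  expect_error(depthCurve(c(1, 2), c(-1, 0)), ">= 0")
})

test_that("advantage depth recovers the analytic exponential crossing", {
  z <- seq(0, 10, by = 0.05)
  tau <- 3
  tum <- depthCurve(z, 2 * exp(-z / tau))
  hea <- depthCurve(z, exp(-z))             # healthy peak 1 at z = 0
  ad <- advantageDepth(tum, hea)
  expect_true(ad$crossed)
  expect_lt(abs(ad$depth - tau * log(2)), 0.05)   # within one grid spacing
  # identical curves cross exactly at the healthy peak depth
  peaked <- depthCurve(z, exp(-(z - 2)^2))
  same <- advantageDepth(peaked, peaked)
  expect_true(same$crossed)
  expect_equal(same$depth, 2, tolerance = 0.05)
  # tumour everywhere below the healthy peak: flagged, no depth
  low <- depthCurve(z, 0.5 * exp(-z))
  expect_false(advantageDepth(low, hea)$crossed)
  expect_true(is.na(advantageDepth(low, hea)$depth))
  expect_error(advantageDepth(depthCurve(1, 1), depthCurve(5, 1)), "overlap")
})

test_that("advantage depth agrees with a dense brute-force scan", {
  set.seed(5)
  z <- seq(0, 12, by = 0.25)
  zf <- seq(0, 12, by = 0.025)       # 10x resolution
  for (i in 1:10) {
    a <- runif(1, 1.2, 3); tau <- runif(1, 2, 6); mu <- runif(1, 0.5, 2)
    tum <- a * exp(-z / tau)
    hea <- exp(-(z - mu)^2 / 2)
    ad <- advantageDepth(depthCurve(z, tum), depthCurve(z, hea))
    # brute force on the fine grid
    heaF <- approx(z, hea, zf)$y
    tumF <- approx(z, tum, zf)$y
    pk <- max(heaF); ipk <- which.max(heaF)
    cross <- which(tumF[ipk:length(zf)] <= pk)
    if (length(cross) && max(tumF) >= pk) {
      bf <- zf[ipk + cross[1] - 1]
      expect_true(ad$crossed)
      expect_lt(abs(ad$depth - bf), 0.25)   # within one coarse spacing
    } else {
      expect_false(ad$crossed)
    }
  }
})

test_that("isodose widths match analytic profiles", {
  # Gaussian: FWHM = 2 sigma sqrt(2 ln 2), checked on a dense resampling
  sigma <- 1.7
  x <- seq(-6 * sigma, 6 * sigma, length.out = 1e4)
  prof <- lateralProfile(x, exp(-x^2 / (2 * sigma^2)))
  w50 <- isodoseWidth(prof, 0.5)
  expect_false(w50$flagged)
  expect_lt(abs(w50$width - 2 * sigma * sqrt(2 * log(2))), 1e-6)
  w80 <- isodoseWidth(prof, 0.8)
  expect_lt(abs(w80$width - 2 * sigma * sqrt(2 * log(1 / 0.8))), 1e-6)
  # rectangle of width W has width W at every level
  xr <- seq(-10, 10, by = 0.01)
  rect <- lateralProfile(xr, as.numeric(abs(xr) <= 4))
  expect_equal(isodoseWidth(rect, 0.5)$width, 8, tolerance = 0.011)
  expect_equal(isodoseWidth(rect, 0.8)$width, 8, tolerance = 0.011)
  expect_error(isodoseWidth(prof, 1.2), "inside")
  expect_error(isodoseWidth(lateralProfile(1:3, c(0, 0, 0)), 0.5),
               "positive maximum")
  # profile that never falls below the level on one side is flagged
  half <- lateralProfile(seq(0, 5, 0.1), exp(-seq(0, 5, 0.1)))
  expect_true(isodoseWidth(half, 0.5)$flagged)
})

test_that("the 50% width is never narrower than the 80% width", {
  set.seed(9)
  for (i in 1:25) {
    x <- seq(-8, 8, length.out = 201)
    v <- abs(stats::filter(runif(201), rep(1, 15), sides = 2))
    v[is.na(v)] <- 0
    if (max(v) <= 0) next
    p <- lateralProfile(x, v)
    expect_gte(isodoseWidth(p, 0.5)$width, isodoseWidth(p, 0.8)$width)
  }
})

test_that("isodose widths agree with an independent interpolation oracle", {
  sigma <- 2.2
  x <- seq(-10, 10, length.out = 1e4)
  v <- exp(-x^2 / (2 * sigma^2))
  for (lev in c(0.5, 0.8)) {
    thr <- lev * max(v)
    f <- stats::approxfun(x, v)
    left <- stats::uniroot(function(t) f(t) - thr, c(-10, 0),
                           tol = 1e-12)$root
    right <- stats::uniroot(function(t) f(t) - thr, c(0, 10),
                            tol = 1e-12)$root
    w <- isodoseWidth(lateralProfile(x, v), lev)$width
    expect_lt(abs(w - (right - left)), 1e-6)
  }
})

test_that("gap sweeps are reproducible and keep failed rows flagged", {
  src <- defaultSource()
  cfg <- runConfig(5e3, seed = 21)
  t1 <- gapSweep("standard", c(0, 5), src, cfg)
  t2 <- gapSweep("standard", c(0, 5), src, cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 2)
  expect_true(all(t1$ok))
  expect_true(all(t1$width50 >= t1$width80))
  # an invalid gap produces a flagged row, not a dropped one
  t3 <- gapSweep("standard", c(-1, 0), src, cfg)
  expect_equal(nrow(t3), 2)
  expect_false(t3$ok[1])
  expect_true(nzchar(t3$note[1]))
})
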