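test_that("source sampling honours the disk, spectrum and determinism", {
  s0 <- sourceModel(diskRadius = 0, groupSpectrum = c(0, 1, 0),
                    photonFraction = 0)
  p <- sampleSource(s0, 500, seed = 3)
  expect_true(all(p$x == 0 & p$y == 0 & p$z == 0))
  expect_true(all(p$group == 2))          # every neutron epithermal
  expect_true(all(p$species == "neutron"))
  expect_true(all(p$weight == 1))
  expect_true(all(abs(p$ux^2 + p$uy^2 + p$uz^2 - 1) < 1e-12))
  expect_true(all(p$uz > 0))
  # forward-peaking limit: cos^n with huge n collapses onto +z
  pf <- sampleSource(sourceModel(angularExponent = 1e12, photonFraction = 0),
                     200, seed = 1)
  expect_true(all(pf$uz > 1 - 1e-9))
  # positions within the disk, uniform seed reproducibility
  s1 <- sourceModel(diskRadius = 7.5)
  a <- sampleSource(s1, 300, seed = 9)
  b <- sampleSource(s1, 300, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$x^2 + a$y^2 <= 7.5^2))
  expect_error(sourceModel(groupSpectrum = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("pure-absorber slab transmission matches exp(-sigma d)", {
  src <- pencilSource()
  for (sd in c(0.5, 2)) {
    sc <- absorberSlabScene(sd, 1)
    run <- runTransport(sc, src, runConfig(4e4, seed = 17), cylTally(c(0, 2), 1, 2, 2))
    s <- run$summary
    trans <- s$escaped / s$emitted
    p <- exp(-sd)
    sigma <- sqrt(p * (1 - p) / s$nHistories)
    expect_lt(abs(trans - p), 3 * sigma)
  }
})

test_that("a void scene lets all weight escape without looping", {
  run <- runTransport(vacuumScene(), pencilSource(), runConfig(2e3, seed = 1),
                      cylTally(c(0, 10), 5, 5, 5))
  s <- run$summary
  expect_equal(s$escaped, s$emitted)
  expect_equal(s$absorbed, 0)
})

test_that("weight balance holds to 1e-9 on every run", {
  src <- defaultSource()
  scenes <- list(makeWaterPhantomScene("standard", 2),
                 makeCubicPhantomScene("extended5", 1),
                 absorberSlabScene(1, 1))
  for (sc in scenes) {
    s <- runTransport(sc, src, runConfig(5e3, seed = 4),
                      cylTally(c(0, 10), 2, 5, 2.5))$summary
    expect_lt(weightBalance(s), 1e-9)
  }
})

test_that("identical seeds give bit-identical tallies", {
  sc <- makeWaterPhantomScene("standard", 0)
  src <- defaultSource()
  cfg <- runConfig(1e4, seed = 123)
  t1 <- runTransport(sc, src, cfg, cylTally(c(30, 40), 1, 6, 1))
  t2 <- runTransport(sc, src, cfg, cylTally(c(30, 40), 1, 6, 1))
  expect_identical(t1$tallies[[1]]@flux, t2$tallies[[1]]@flux)
  expect_identical(t1$summary$absorbed, t2$summary$absorbed)
  # a different seed gives different results
  t3 <- runTransport(sc, src, runConfig(1e4, seed = 124),
                     cylTally(c(30, 40), 1, 6, 1))
  expect_false(identical(t1$tallies[[1]]@flux, t3$tallies[[1]]@flux))
})

test_that("relative errors follow the batch-statistics formula", {
  expect_equal(relativeError(c(1, 2, 3)), (1 / sqrt(3)) / 2,
               tolerance = 1e-12)
  expect_equal(relativeError(c(2, 2, 2, 2)), 0)
  expect_true(is.na(relativeError(c(0, 0, 0))))
  expect_error(relativeError(matrix(1, 2, 1)), "2 batches")
  m <- rbind(c(1, 2, 3), c(5, 5, 5))
  expect_equal(relativeError(m), c((1 / sqrt(3)) / 2, 0))
})

test_that("relative error shrinks like one over root n", {
  sc <- makeWaterPhantomScene("standard", 0)
  src <- defaultSource()
  tal <- cylTally(c(30.2, 40.2), 1, 4, 2)
  r1 <- runTransport(sc, src, runConfig(2e4, seed = 6), tal)$tallies[[1]]
  r2 <- runTransport(sc, src, runConfig(8e4, seed = 6), tal)$tallies[[1]]
  e1 <- stats::median(r1@relErr[, , 3], na.rm = TRUE)
  e2 <- stats::median(r2@relErr[, , 3], na.rm = TRUE)
  # quadrupling histories should halve the error, within batch noise
  expect_gt(e1 / e2, 1.4)
  expect_lt(e1 / e2, 2.9)
})

test_that("batch error estimate agrees with replicate spread", {
  sc <- makeWaterPhantomScene("standard", 0)
  src <- defaultSource()
  tal <- cylTally(c(32, 36), 4, 4, 4)  # one coarse bin at depth
  vals <- numeric(20); errs <- numeric(20)
  for (k in 1:20) {
    tg <- runTransport(sc, src, runConfig(4e3, seed = 100 + k),
                       tal)$tallies[[1]]
    vals[k] <- tg@flux[1, 1, 3]
    errs[k] <- tg@relErr[1, 1, 3]
  }
  empirical <- sd(vals) / mean(vals)
  reported <- mean(errs)
  expect_lt(reported / empirical, 1.5)
  expect_gt(reported / empirical, 1 / 1.5)
})

test_that("downscatter-only physics never populates upper groups", {
  # pure thermal source into water: epithermal and fast flux identically 0
  src <- sourceModel(diskRadius = 2, groupSpectrum = c(0, 0, 1),
                     photonFraction = 0)
  sc <- makeWaterPhantomScene("standard", 0)
  tg <- runTransport(sc, src, runConfig(5e3, seed = 2),
                     cylTally(c(30, 40), 1, 6, 1))$tallies[[1]]
  expect_true(all(tg@flux[, , 1] == 0))
  expect_true(all(tg@flux[, , 2] == 0))
  expect_gt(sum(tg@flux[, , 3]), 0)
})

test_that("surface scans are axisymmetric and reject buried positions", {
  sc <- buildScene(buildCollimator("standard"), 0, NULL)
  src <- defaultSource()
  pos <- rbind(c(8, 0, 33), c(-8, 0, 33))  # mirrored across the axis
  scan <- surfaceScan(sc, src, runConfig(4e4, seed = 8), pos, radius = 1.5)
  sig <- sqrt(sum((scan$thermalFlux * scan$thermalRelErr)^2))
  expect_lt(abs(scan$thermalFlux[1] - scan$thermalFlux[2]), 3 * sig + 1e-12)
  expect_error(surfaceScan(sc, src, runConfig(1e3, seed = 1),
                           rbind(c(12, 0, 15))), "inside")
})

test_that("run configuration rejects invalid precision controls", {
  expect_error(runConfig(0), "nHistories")
  expect_error(runConfig(10, batches = 20), "batches")
  expect_error(runConfig(100, weightCutoff = 0.1, rouletteSurvival = 0.01),
               "weightCutoff")
})
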