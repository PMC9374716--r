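test_that("default group scheme satisfies the multigroup invariants", {
  gs <- defaultGroupScheme()
  expect_s4_class(gs, "EnergyGroupScheme")
  expect_identical(nGroups(gs), 3L)
  expect_true(all(diff(gs@boundaries) < 0))
  expect_true(gs@cadmiumCutoff %in% gs@boundaries[-c(1, 4)])
  expect_identical(groupLabels(gs)[3], "thermal")
  # degenerate schemes are rejected
  expect_error(energyGroupScheme(c(1e7, 0.5), "thermal", 0.5))
  expect_error(energyGroupScheme(c(1e7, 1e4, 0.5, 1e-4),
                                 c("fast", "epithermal", "thermal"), 7),
               "cadmium")
})

test_that("bundled materials satisfy the cross-section invariants", {
  mats <- defaultMaterials()
  expect_true(all(c("water", "tissue", "air", "lif_polyethylene",
                    "acrylic") %in% names(mats)))
  for (m in mats) {
    expect_true(validObject(m))
    # closure: sigma_total partitions exactly into absorption + scattering
    expect_equal(sigmaTotal(m), m@sigmaAbs + rowSums(m@scatterMatrix))
    expect_true(all(m@sigmaAbs >= 0) && all(m@scatterMatrix >= 0))
    expect_lt(abs(sum(m@weightFractions) - 1), 1e-6)
    # no upscatter out of the thermal group
    expect_identical(unname(m@scatterMatrix[3, 1:2]), c(0, 0))
  }
  # the cubic-phantom tissue composition
  ti <- mats$tissue
  expect_equal(unname(ti@weightFractions[c("H", "C", "N", "O")]),
               c(0.10, 0.10, 0.03, 0.77))
  expect_equal(ti@density, 1)
  expect_error(materialSpec("bad", 1, c(H = 0.5), sigmaAbs = rep(0, 3),
                            scatterMatrix = matrix(0, 3, 3)),
               "sum to 1")
})

test_that("collimator variants have the printed aperture and exit planes", {
  std <- buildCollimator("standard", 12, 30)
  expect_equal(std@extensionLength, 0)
  expect_equal(unname(std@taperProfile[nrow(std@taperProfile), "r"]), 6)
  expect_equal(unname(std@taperProfile[1, "r"]), 15)
  e5 <- buildCollimator("extended5"); e10 <- buildCollimator("extended10")
  expect_equal(exitPlane(e5), exitPlane(std) + 5)
  expect_equal(exitPlane(e10), exitPlane(std) + 10)
  for (c in list(std, e5, e10)) {
    expect_true(all(diff(c@taperProfile[, "r"]) <= 0))
    expect_equal(range(c@taperProfile[, "r"]), c(6, 15))
  }
  expect_error(buildCollimator("bent"), "standard, extended5, extended10")
  expect_error(buildCollimator("standard", 30, 12), "smaller")
  expect_error(buildCollimator("standard", -1, 30), "positive")
})

test_that("scene building places the phantom at exit + gap", {
  sc0 <- makeWaterPhantomScene("standard", 0)
  expect_equal(phantomFront(sc0), exitPlane(buildCollimator("standard")))
  expect_error(buildScene(buildCollimator("standard"), -1,
                          boxPhantom("water", c(10, 10, 10))),
               ">= 0")
  # equal source-to-surface distance: (standard, g) vs (extendedL, g - L)
  for (g in c(5, 10)) {
    a <- makeWaterPhantomScene("standard", g)
    b <- makeWaterPhantomScene(if (g == 5) "extended5" else "extended10", 0)
    expect_equal(sourceToSurface(a), sourceToSurface(b))
  }
})

test_that("locate is total and deterministic over random points", {
  sc <- makeWaterPhantomScene("standard", 5)
  set.seed(1)
  pts <- cbind(runif(1e4, -30, 30), runif(1e4, -30, 30), runif(1e4, -15, 80))
  m1 <- locate(sc, pts)
  m2 <- locate(sc, pts)
  expect_identical(m1, m2)
  expect_true(all(m1 %in% names(sc@materials)))
  # a few known points
  expect_identical(locate(sc, c(0, 0, 40)), "water")
  expect_identical(locate(sc, c(200, 0, 0)), "air")
  expect_identical(locate(sc, c(12, 0, 15)), "lif_polyethylene")
  expect_error(locate(sc, c(0, 0, Inf)), "finite")
})

test_that("distance_to_boundary matches the analytic ray-cylinder chord", {
  sc <- buildScene(buildCollimator("standard"), 0, NULL)
  # radial ray hits the outer wall cylinder (R = 20) from x = 30
  d <- distanceToBoundary(sc, c(30, 0, 15), c(-1, 0, 0))
  expect_equal(d$length, 10, tolerance = 1e-9)
  expect_identical(d$nextMaterial, "lif_polyethylene")
  # oblique ray: closed-form quadratic oracle for the cylinder crossing
  p <- c(30, 4, 15); dir <- c(-0.8, -0.2, 0.1)
  dir <- dir / sqrt(sum(dir^2))
  R <- 20
  a <- dir[1]^2 + dir[2]^2
  b <- 2 * (p[1] * dir[1] + p[2] * dir[2])
  cc <- p[1]^2 + p[2]^2 - R^2
  tstar <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
  d2 <- distanceToBoundary(sc, p, dir)
  expect_equal(d2$length, tstar, tolerance = 1e-8)
  # unnormalised directions are rejected; outward rays escape
  expect_error(distanceToBoundary(sc, c(0, 0, 5), c(0, 0, 2)), "normalised")
  out <- distanceToBoundary(sc, c(100, 0, 200), c(0.6, 0.8, 0))
  expect_identical(out$nextMaterial, "escape")
})

test_that("boundary walking reproduces the ray-marched material sequence", {
  sc <- makeWaterPhantomScene("standard", 3)
  rays <- list(list(p = c(0, 0, -5), d = c(0, 0, 1)),
               list(p = c(-25, 2, 10), d = c(1, 0, 0.4)),
               list(p = c(10, -10, 60), d = c(-0.3, 0.3, -0.9)))
  for (ray in rays) {
    d <- ray$d / sqrt(sum(ray$d^2))
    # walk boundaries
    p <- ray$p; walked <- locate(sc, p); travelled <- 0
    repeat {
      st <- distanceToBoundary(sc, p, d)
      if (!is.finite(st$length) || st$nextMaterial == "escape" ||
          travelled > 150) break
      p <- p + (st$length + 1e-6) * d
      travelled <- travelled + st$length
      walked <- c(walked, locate(sc, p))
    }
    walked <- rle(walked)$values
    # fine ray-march (ending slightly past the last boundary nudge)
    tt <- c(seq(0, travelled, by = 0.005), travelled + 2e-3)
    marched <- rle(locate(sc, cbind(ray$p[1] + tt * d[1],
                                    ray$p[2] + tt * d[2],
                                    ray$p[3] + tt * d[3])))$values
    expect_identical(walked, marched)
  }
})
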