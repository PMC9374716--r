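test_that("the water phantom has the published box dimensions", {
  sc <- makeWaterPhantomScene("standard", 0)
  fr <- phantomFront(sc)
  # 2 mm acrylic front wall, then 21 cm of water along the beam
  expect_identical(locate(sc, c(0, 0, fr + 0.1)), "acrylic")
  expect_identical(locate(sc, c(0, 0, fr + 0.3)), "water")
  expect_identical(locate(sc, c(0, 0, fr + 0.2 + 20.9)), "water")
  expect_identical(locate(sc, c(0, 0, fr + 0.2 + 21.5)), "acrylic")
  # interior width 21 cm (x), height 28 cm (y), 1 cm side walls
  zmid <- fr + 10
  expect_identical(locate(sc, c(10.4, 0, zmid)), "water")
  expect_identical(locate(sc, c(10.6, 0, zmid)), "acrylic")
  expect_identical(locate(sc, c(11.6, 0, zmid)), "air")
  expect_identical(locate(sc, c(0, 13.9, zmid)), "water")
  expect_identical(locate(sc, c(0, 14.5, zmid)), "acrylic")
  # phantom front abuts the exit plane at zero gap
  expect_equal(fr, exitPlane(buildCollimator("standard")))
})

test_that("the cubic phantom carries the printed composition and boron", {
  sc <- makeCubicPhantomScene("standard", 5)
  expect_equal(sc@phantom$boron, 25)
  ti <- sc@materials$tissue
  expect_equal(unname(ti@weightFractions[c("H", "C", "N", "O")]),
               c(0.1, 0.1, 0.03, 0.77))
  expect_equal(ti@density, 1)
  expect_equal(sc@phantom$size, c(30, 30, 30))
  expect_equal(sourceToSurface(sc), 35)
  expect_identical(locate(sc, c(0, 0, phantomFront(sc) + 15)), "tissue")
})

test_that("head-and-neck phantoms follow the case placement rules", {
  for (id in c("nasopharynx", "hypopharynx")) {
    hn <- makeHeadNeckPhantom(headNeckCase(id, seed = 3))
    vp <- hn$phantom
    expect_equal(vp@voxelEdge, 0.3)
    lm <- vp@labelMap
    tl <- lm$label[lm$organ == "tumour"]
    vol <- sum(vp@labels == tl) * vp@voxelEdge^3
    expect_lt(abs(vol - 1), vp@voxelEdge^3 + 1e-9)   # 1 cm^3 within a voxel
    # tumour fully inside the body (never adjacent to air labels directly)
    expect_false(any(vp@labels == tl & vp@labels == 1L))
    # organ list covers the DVH table rows
    need <- c("tumour", "mucosa", "body", "brain", "brainstem",
              "spinal cord", "eye_l", "eye_r", "esophagus", "parotid_l",
              "parotid_r", "thyroid", "mandible")
    if (id == "hypopharynx") need <- c(need, "lung")
    expect_true(all(need %in% names(organMasks(vp))))
    expect_true(validObject(vp))
    expect_true(validObject(hn$scene@collimator))
  }
  # nasopharynx tumour sits about 6 cm deep along the beam axis
  hn1 <- makeHeadNeckPhantom(headNeckCase("nasopharynx", seed = 1))
  vp1 <- hn1$phantom
  idx <- which(vp1@labels == vp1@labelMap$label[
    vp1@labelMap$organ == "tumour"], arr.ind = TRUE)
  depth <- mean(idx[, 3] - 0.5) * vp1@voxelEdge
  expect_lt(abs(depth - 6), 0.3)
})

test_that("phantom generation is deterministic for a fixed seed", {
  a <- makeHeadNeckPhantom(headNeckCase("nasopharynx", seed = 11))$phantom
  b <- makeHeadNeckPhantom(headNeckCase("nasopharynx", seed = 11))$phantom
  expect_identical(a@labels, b@labels)
  c <- makeHeadNeckPhantom(headNeckCase("nasopharynx", seed = 12))$phantom
  expect_false(identical(a@labels, c@labels))
})

test_that("synthetic measurements sample the truth with configured noise", {
  z <- seq(0, 20, by = 0.1)
  truth <- data.frame(position = z, value = 100 * exp(-z / 8))
  # zero-noise configuration reads back the truth at the sampled spacing
  ms0 <- synthMeasurement(truth, spacing = 0.5, noise = NULL)
  expect_equal(ms0$reading, ms0$truth)
  expect_equal(diff(ms0$position)[1], 0.5)
  # fixed seed reproduces readings; different seed does not
  m1 <- synthMeasurement(truth, noise = list(cv = 0.05), seed = 4)
  m2 <- synthMeasurement(truth, noise = list(cv = 0.05), seed = 4)
  m3 <- synthMeasurement(truth, noise = list(cv = 0.05), seed = 5)
  expect_identical(m1$reading, m2$reading)
  expect_false(identical(m1$reading, m3$reading))
  expect_true(all(m1$reading >= 0))
  expect_error(synthMeasurement(truth, noise = list(cv = 0)), "> 0")
  expect_error(synthMeasurement(data.frame(position = z, value = 0 * z)),
               "positive")
})

test_that("the configured CV is recovered from replicate readings", {
  truth <- data.frame(position = c(0, 1), value = c(50, 50))
  reads <- vapply(1:200, function(k)
    synthMeasurement(truth, spacing = 1, noise = list(cv = 0.05),
                     seed = k)$reading[1], numeric(1))
  cv <- sd(reads) / mean(reads)
  expect_gt(cv, 0.035)
  expect_lt(cv, 0.065)
})

test_that("exponential attenuation constants are recovered from scans", {
  z <- seq(0, 30, by = 0.2)
  lambda <- 12.5
  truth <- data.frame(position = z, value = 7e-4 * exp(-z / lambda))
  fit <- fitAttenuation(synthMeasurement(truth, spacing = 1, noise = NULL))
  expect_lt(abs(fit$lambda - lambda) / lambda, 0.01)
  expect_equal(fit$amplitude, 7e-4, tolerance = 1e-6)
})

test_that("cadmium differencing isolates the sub-cutoff component", {
  z <- seq(0, 10, by = 1)
  truth <- data.frame(position = z, value = 10 + z)
  bare <- synthMeasurement(truth, spacing = 1, noise = NULL)
  covered <- synthMeasurement(data.frame(position = z, value = rep(4, 11)),
                              spacing = 1, noise = NULL)
  cd <- cadmiumDifference(bare, covered)
  expect_equal(cd$thermal, (10 + z) - 4)
  expect_true(all(cd$thermal >= 0))
})
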