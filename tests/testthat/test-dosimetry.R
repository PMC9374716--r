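test_that("tissue boron concentrations follow the tissue-to-blood ratios", {
  expect_equal(boronConcentration("tumour", 25), 87.5)    # 3.5 x 25
  expect_equal(boronConcentration("soft tissue", 25), 25)
  expect_equal(boronConcentration("air", 25), 0)
  expect_equal(boronConcentration("mucosa", 25), 25)
  expect_error(boronConcentration("gristle", 25), "known tissues")
  expect_error(boronConcentration("tumour", -1), ">= 0")
})

test_that("weighted dose reproduces the tumour, skin and air hand sums", {
  expect_equal(weightedDose(doseComponents(1, 1, 1, 1), "tumour"),
               3.8 + 2.9 + 2.4 + 1)                       # 10.1
  expect_equal(weightedDose(doseComponents(1, 0, 0, 0), "skin"), 2.5)
  expect_equal(weightedDose(doseComponents(2, 5, 1, 3), "air"), 0)
  expect_equal(weightedDose(doseComponents(0, 1, 0, 0), "water"), 0)
  expect_error(weightedDose(doseComponents(1, 0, 0, 0), "gristle"),
               "known tissues")
})

test_that("weighted dose is linear in every component", {
  set.seed(42)
  params <- defaultWeightingParams()
  for (i in 1:20) {
    c1 <- doseComponents(runif(1), runif(1), runif(1), runif(1))
    c2 <- doseComponents(runif(1), runif(1), runif(1), runif(1))
    k <- runif(1, 0, 5)
    tis <- sample(tissues(params), 1)
    sumc <- doseComponents(c1$boron + k * c2$boron,
                           c1$nitrogen + k * c2$nitrogen,
                           c1$hydrogen + k * c2$hydrogen,
                           c1$gamma + k * c2$gamma)
    expect_equal(weightedDose(sumc, tis, params),
                 weightedDose(c1, tis, params) +
                   k * weightedDose(c2, tis, params))
  }
})

test_that("unit weights with no boron reduce weighted to physical dose", {
  ones <- new("WeightingParams",
              table = data.frame(CBE = 1, RBE_N = 1, RBE_H = 1,
                                 RBE_gamma = 1, tissueToBlood = 1,
                                 row.names = "flat"))
  set.seed(7)
  cmp <- doseComponents(0, runif(1), runif(1), runif(1))
  expect_equal(weightedDose(cmp, "flat", ones), totalDose(cmp))
})

test_that("physical dose assembles the four components from fluence", {
  mats <- defaultMaterials()
  z <- physicalDose(c(0, 0, 0), mats$tissue, boron = 25,
                    photonEnergyFluence = 0)
  expect_equal(totalDose(z), 0)
  # boron concentration zero kills the boron component regardless of flux
  d0 <- physicalDose(c(1e8, 1e9, 1e9), mats$tissue, boron = 0)
  expect_equal(d0$boron, 0)
  # unit thermal factor and w_N = 0.03: nitrogen = 0.03 * phi
  k <- new("KermaSet", boronFactor = c(0, 0, 0),
           nitrogenFactor = c(0, 0, 1), hydrogenFactor = c(0, 0, 0),
           photonFactor = 0, version = 0)
  phi <- 3.7e8
  d <- physicalDose(c(0, 0, phi), mats$tissue, boron = 0, kerma = k)
  expect_equal(d$nitrogen, 0.03 * phi)
  expect_error(physicalDose(c(-1, 0, 0), mats$tissue), ">= 0")
})

test_that("the four-way component split always sums to the total", {
  mats <- defaultMaterials()
  set.seed(11)
  flux <- matrix(10^runif(30, 5, 9), nrow = 3)
  pf <- 10^runif(10, 5, 8)
  cmp <- physicalDose(flux, mats$tissue, boron = 25,
                      photonEnergyFluence = pf)
  expect_equal(cmp$boron + cmp$nitrogen + cmp$hydrogen + cmp$gamma,
               totalDose(cmp))
  expect_true(all(totalDose(cmp) > 0))
})

test_that("irradiation time is the prescription over the peak rate", {
  # 0.2 Gy_w/min peak with a 12 Gy_w prescription takes 60 minutes
  it <- irradiationTime(c(0.05, 0.2, 0.1), prescription = prescriptionSpec())
  expect_equal(it$minutes, 60)
  expect_equal(it$minutes * 0.2, 12)             # time x max rate = dose
  # doubling the rate (i.e. source intensity) halves the time exactly
  it2 <- irradiationTime(2 * c(0.05, 0.2, 0.1))
  expect_equal(it2$minutes, 30)
  expect_error(irradiationTime(c(1, 2), mask = logical(2)), "empty")
  expect_error(irradiationTime(c(0, 0)), "unreachable")
  expect_error(prescriptionSpec(dose = 0), "> 0")
})

test_that("plan dose normalises the mucosa maximum to the prescription", {
  vp <- tinyVoxelPhantom()
  scene <- buildScene(NULL, 0, voxelPhantomRegion(vp))
  tg <- uniformVoxelTally(dim(vp@labels))
  plan <- planDose(scene, tg, intensity = 1e12)
  mucosa <- vp@labels == 3
  expect_equal(max(plan$weighted[mucosa]), 12)
  # tumour voxels beat soft-tissue voxels under identical fluence:
  # CBE 3.8 >= 1.34 and boron ratio 3.5 >= 1
  expect_gt(min(plan$weighted[vp@labels == 4]),
            max(plan$weighted[vp@labels == 2]))
  # air voxels get zero weighted dose
  expect_equal(max(plan$weighted[vp@labels == 1]), 0)
  expect_gt(plan$minutes, 0)
})

test_that("plan dose rejects unmapped labels and unreachable prescriptions", {
  vp <- tinyVoxelPhantom()
  scene <- buildScene(NULL, 0, voxelPhantomRegion(vp))
  tg <- uniformVoxelTally(dim(vp@labels))
  # all-zero fluence: mucosa prescription unreachable
  tg0 <- uniformVoxelTally(dim(vp@labels), flux = c(0, 0, 0), photon = 0)
  expect_error(planDose(scene, tg0), "unreachable")
  # a label mapping to an unknown tissue is named
  vpBad <- vp
  vpBad@labelMap$tissue[4] <- "gristle"
  sceneBad <- buildScene(NULL, 0, voxelPhantomRegion(vpBad))
  expect_error(planDose(sceneBad, tg), "gristle")
})

test_that("default weighting table satisfies its invariants", {
  wp <- defaultWeightingParams()
  tb <- wp@table
  expect_equal(unname(unlist(tb["air", ])), rep(0, 5))
  expect_equal(tb["water", "RBE_N"], 0)
  expect_equal(tb["tumour", "tissueToBlood"], 3.5)
  expect_true(all(as.matrix(tb) >= 0))
  # the mucosa row defaults to soft tissue and is overridable
  expect_equal(tb["mucosa", "CBE"], tb["soft tissue", "CBE"])
  expect_equal(defaultWeightingParams(mucosaCBE = 4.9)@table["mucosa", "CBE"],
               4.9)
})
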