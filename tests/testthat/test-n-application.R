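toyHier <- function() {
  adminHierarchy(
    countries = "C01", counties = c("C01_c1", "C01_c2"),
    countyCountry = c(C01_c1 = "C01", C01_c2 = "C01"),
    membership = c("C01_c1", "C01_c1", "C01_c2", "C01_c2"),
    regions = c(C01 = "R1"))
}

test_that("county amounts extend past the prior by national ratios only", {
  hier <- toyHier()
  priorYrs <- as.character(2013:2014)
  yrs <- as.character(2013:2016)
  prior <- array(c(5, 10, 6, 10), c(1, 2, 2),
                 dimnames = list("SN", hier@counties, priorYrs))
  fao <- array(c(11, 16, 19.2, 16), c(1, 1, 4),
               dimnames = list("SN", "C01", yrs))
  out <- extendNAmount(prior, fao, hier, pivotYear = 2014L)
  # years <= 2014 untouched
  expect_equal(out[, , priorYrs], prior[, , priorYrs])
  # national ratio 19.2/16 = 1.2 applied to the 2014 county values
  expect_equal(unname(out["SN", , "2015"]), c(6, 10) * 1.2)
  # flat national series after the pivot keeps county values at their 2014 level
  expect_equal(unname(out["SN", , "2016"]), c(6, 10))
})

test_that("SN correction scales counties by the national factor, MA/CR pass", {
  hier <- toyHier()
  yrs <- "2000"
  panel <- array(c(44, 10, 3, 44, 12, 5), c(3, 2, 1),
                 dimnames = list(c("SN", "MA", "CR"), hier@counties, yrs))
  fao <- array(c(100, 99, 99), c(3, 1, 1),
               dimnames = list(c("SN", "MA", "CR"), "C01", yrs))
  out <- correctSnToNational(panel, fao, hier)
  # Wang total 88 vs FAO 100: every county SN scaled by 1/0.88
  expect_equal(unname(out["SN", , 1]), c(44, 44) / 0.88)
  expect_equal(sum(out["SN", , 1]), 100)
  # MA and CR identical before and after
  expect_equal(out["MA", , ], panel["MA", , ])
  expect_equal(out["CR", , ], panel["CR", , ])
  # factor 1 when already matching
  fao["SN", , ] <- 88
  expect_equal(correctSnToNational(panel, fao, hier), panel)
  # cropland-use fraction rescales the national SN target
  out2 <- correctSnToNational(panel, fao, hier, croplandUseFraction = 0.5)
  expect_equal(sum(out2["SN", , 1]), 44)
})

test_that("constant-ratio split conserves amounts and scales linearly", {
  refRate <- array(c(50, 100, 50, 100, 50, 100), c(2, 3, 1),
                   dimnames = list(c("Wheat", "Maize"),
                                   c("SN", "MA", "CR"), "C01_c1"))
  harea <- array(10, c(2, 1, 1),
                 dimnames = list(c("Wheat", "Maize"), "C01_c1", "2000"))
  namount <- array(c(3000, 1500, 750), c(3, 1, 1),
                   dimnames = list(c("SN", "MA", "CR"), "C01_c1", "2000"))
  rates <- scaleCropRates(namount, refRate, harea)
  # hand evaluation: denominator 50*10 + 100*10 = 1500, factor 2
  expect_equal(unname(rates[, "SN", 1, 1]), c(100, 200))
  expect_equal(sum(rates[, "SN", 1, 1] * harea[, 1, 1]), 3000)
  # linearity: doubling the amount doubles every crop rate
  rates2 <- scaleCropRates(namount * 2, refRate, harea)
  expect_equal(rates2, rates * 2)
  # factor 1 when the amount equals the implied reference amount
  namount["SN", , ] <- 1500
  expect_equal(unname(scaleCropRates(namount, refRate, harea)[, "SN", 1, 1]),
               c(50, 100))
  # zero denominator with positive amount: rates stay 0, flagged
  harea0 <- harea * 0
  expect_warning(r0 <- scaleCropRates(namount, refRate, harea0),
                 "unallocatable")
  expect_true(all(r0 == 0))
})

test_that("the FUBC reference-year map is the published piecewise rule", {
  expect_identical(fubcReferenceYear(c(2003, 2005, 2006)), rep(2006L, 3))
  expect_identical(fubcReferenceYear(c(2007, 2008)), rep(2007L, 2))
  expect_identical(fubcReferenceYear(c(2009, 2011, 2012)), rep(2010L, 3))
  expect_identical(fubcReferenceYear(c(2013, 2014, 2016)), rep(2014L, 3))
  expect_identical(fubcReferenceYear(c(2017, 2018, 2020)), rep(2018L, 3))
  expect_identical(fubcReferenceYear(c(1961, 1999, 2002)),
                   rep(NA_integer_, 3))
})

test_that("FUBC calibration rescales group SN rates to the survey amounts", {
  hier <- toyHier()
  v <- nfertVocabulary()
  yrs <- as.character(2005:2007)
  crops <- c("Wheat", "Barley")  # Wheat group "Wheat", Barley "Other cereals"
  rates <- array(1, c(2, 3, 2, 3),
                 dimnames = list(crops, c("SN", "MA", "CR"), hier@counties,
                                 yrs))
  rates["Wheat", "SN", , ] <- 4
  rates["Barley", "SN", , ] <- 2
  harea <- array(10, c(2, 2, 3), dimnames = list(crops, hier@counties, yrs))
  # pre-calibration Wheat group amount at 2006: 4 * 10 * 2 counties = 80
  anchors <- array(0, c(11, 1, 1),
                   dimnames = list(v$fubcCropGroups, "C01", "2006"))
  anchors["Wheat", , ] <- 100            # factor 1.25
  anchors["Other cereals", , ] <- 40     # factor 1 (2 * 10 * 2 = 40)
  out <- calibrateToFubc(rates, harea, list(anchors = anchors), v, hier)
  # 2005 and 2006 map to the 2006 anchor; 2007 has no anchor table entry
  expect_equal(unname(out["Wheat", "SN", 1, ]), c(5, 5, 4))
  expect_equal(unname(out["Barley", "SN", 1, ]), rep(2, 3))
  # re-summed anchor-year group amount equals the survey value
  expect_equal(sum(out["Wheat", "SN", , "2006"] * harea["Wheat", , "2006"]),
               100)
  # MA/CR and pre-2003 years untouched
  expect_equal(out[, "MA", , ], rates[, "MA", , ])
  yrsEarly <- as.character(1999:2001)
  ratesE <- array(3, c(2, 3, 2, 3),
                  dimnames = list(crops, c("SN", "MA", "CR"), hier@counties,
                                  yrsEarly))
  expect_equal(calibrateToFubc(ratesE, harea, list(anchors = anchors), v,
                               hier), ratesE)
})

test_that("rasterized rates broadcast county values and sum over classes", {
  hier <- toyHier()
  grid <- gridDefinition(2, 2, 1)
  rates <- array(0, c(1, 3, 2, 1),
                 dimnames = list("Wheat", c("SN", "MA", "CR"), hier@counties,
                                 "2000"))
  rates["Wheat", , "C01_c1", 1] <- c(100, 30, 10)
  rates["Wheat", , "C01_c2", 1] <- c(200, 40, 20)
  cube <- rasterizeRates(rates, hier, grid)
  expect_equal(unname(cube@byClass["Wheat", "SN", 1, ]),
               c(100, 100, 200, 200))  # step edge at the county boundary
  tot <- totalRate(cube)
  expect_equal(unname(tot["Wheat", 1, ]), c(140, 140, 260, 260))
})

test_that("noise-free reconstruction recovers the true rates everywhere", {
  w <- getTinyWorld()
  run <- getTinyRun()
  gt <- w@groundTruth$rates
  err <- abs(run$napp$rates - gt) / pmax(gt, 1e-9)
  expect_lt(max(err[gt > 0]), 1e-3 / 100)   # far below 0.1 %
  expect_true(all(run$napp$rates >= 0))
})
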