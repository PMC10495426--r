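test_that("national no-till uses census values directly and stays monotone in [0, 1]", {
  w <- getTinyWorld()
  cov <- w@covariatePanel
  drv <- w@notillDrivers
  out <- predictNationalNotill(cov$ruralPopulation, cov$croplandArea,
                               drv$censusNotill, w@hierarchy)
  expect_true(all(out >= 0))
  frac <- out / cov$croplandArea[rownames(out), ]
  expect_true(all(frac <= 1 + 1e-9))
  # census country-years equal the census sums exactly
  for (j in names(drv$censusNotill)) {
    cyrs <- colnames(drv$censusNotill[[j]])
    expect_equal(out[j, cyrs], colSums(drv$censusNotill[[j]]))
  }
  # monotone non-decreasing response over a covariate sweep: cropland per
  # rural capita rises year over year, census covers the first 8 years
  cpcSweep <- seq(0.5, 50, length.out = 20)
  yrs <- paste(2001:2020)
  rp <- matrix(1, 1, 20, dimnames = list("C01", yrs))
  ca <- matrix(cpcSweep, 1, 20, dimnames = list("C01", yrs))
  censusFrac <- 0.4 * plogis(log(cpcSweep[1:8]))
  census <- list(C01 = matrix(censusFrac * cpcSweep[1:8], 1, 8,
                              dimnames = list("C01_c1", yrs[1:8])))
  hier1 <- adminHierarchy("C01", "C01_c1", c(C01_c1 = "C01"),
                          rep("C01_c1", 4), c(C01 = "R1"))
  pred <- predictNationalNotill(rp, ca, census, hier1)
  predFrac <- pred[1, 9:20] / ca[1, 9:20]
  expect_true(all(diff(predFrac) >= -1e-12))
})

test_that("eligibility screening follows income and field size", {
  w <- getTinyWorld()
  run <- getTinyRun()
  drv <- w@notillDrivers
  pot <- allocatePotentialNotill(run$harea$cube, drv, w@vocabulary,
                                 w@hierarchy)
  ctry <- cellCountry(w@hierarchy)
  lowSmall <- drv$incomeClass[ctry] == "low" & drv$fieldSize < 3
  expect_true(all(pot[, lowSmall] == 0))
  # high-income cells keep their potential whatever the field size
  hi <- which(drv$incomeClass[ctry] == "high" & drv$fieldSize == 1)
  suit <- colSums(run$harea$cube@values[w@vocabulary$notillCrops, , hi,
                                        drop = FALSE])
  expect_equal(pot[, hi], suit * rep(drv$rainfedFraction[hi],
                                     each = nrow(pot)))
  # a cell growing only unsuitable crops has zero potential
  cube <- run$harea$cube
  cube@values[, , 1] <- 0
  cube@values["Rice", , 1] <- 100
  pot2 <- allocatePotentialNotill(cube, drv, w@vocabulary, w@hierarchy)
  expect_true(all(pot2[, 1] == 0))
})

test_that("the no-till logit hits its closed-form values", {
  drivers <- list(erosion = 1, aridity = 2, fieldSize = 3)
  params <- list(erosion = list(k = 1, xmid = 1),
                 aridity = list(k = 1, xmid = 2),
                 cropMix = list(k = 1, xmid = 0.5),
                 fieldSize = list(k = 1, xmid = 3))
  # all predictors at their midpoints -> 0.5
  expect_equal(unname(notillProbability(drivers, params,
                                        matrix(0.5, 1, 1))[1, 1]), 0.5)
  # single active predictor with vx - xmid = ln 3 -> 0.75
  expect_equal(unname(notillProbability(drivers, params,
                                        matrix(0.5 + log(3), 1, 1))[1, 1]),
               0.75)
  # saturation for a steep slope
  params$cropMix$k <- 1e6
  expect_equal(unname(notillProbability(drivers, params,
                                        matrix(0.6, 1, 1))[1, 1]), 1,
               tolerance = 1e-9)
  # incomplete parameter blocks are rejected
  expect_error(notillProbability(drivers, params[-1], matrix(0.5, 1, 1)),
               "logit parameters")
})

test_that("ranked allocation matches the brute-force greedy oracle", {
  hier1 <- adminHierarchy("C01", "C01_c1", c(C01_c1 = "C01"),
                          rep("C01_c1", 12), c(C01 = "R1"))
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    pot <- c(stats::runif(n, 0, 100), rep(0, 12 - n))
    prob <- c(stats::runif(n), rep(0, 12 - n))
    target <- stats::runif(1, 0, 1.2 * sum(pot * prob))
    targets <- matrix(target, 1, 1, dimnames = list("C01", "2000"))
    potential <- matrix(pot, 1, 12, dimnames = list("2000", NULL))
    probability <- matrix(prob, 1, 12, dimnames = list("2000", NULL))
    got <- suppressWarnings(
      downscaleNotill(targets, potential, probability, hier1))[1, ]
    oracle <- bruteForceGreedy(min(target, sum(pot * prob)), pot, prob)
    expect_equal(unname(got), oracle, tolerance = 1e-12)
    expect_equal(sum(got), min(target, sum(pot * prob)), tolerance = 1e-9)
  }
  # explicit worked case: probabilities 0.9/0.5/0.1, equal potential
  targets <- matrix(1.2 * 10 * 0.9, 1, 1, dimnames = list("C01", "2000"))
  potential <- matrix(c(10, 10, 10, rep(0, 9)), 1, 12,
                      dimnames = list("2000", NULL))
  probability <- matrix(c(0.9, 0.5, 0.1, rep(0, 9)), 1, 12,
                        dimnames = list("2000", NULL))
  got <- downscaleNotill(targets, potential, probability, hier1)[1, ]
  expect_equal(got[1:3], c(9, 1.8, 0), ignore_attr = TRUE)
  # zero target selects nothing; saturated target selects everything
  targets[] <- 0
  expect_true(all(downscaleNotill(targets, potential, probability,
                                  hier1) == 0))
  targets[] <- sum(potential * probability)
  full <- downscaleNotill(targets, potential, probability, hier1)[1, ]
  expect_equal(full[1:3], c(9, 5, 1), ignore_attr = TRUE)
})

test_that("cell no-till areas split across crops by harvested-area share", {
  grid <- gridDefinition(1, 2, 1)
  vals <- array(0, c(2, 1, 2),
                dimnames = list(c("Wheat", "Maize"), "2000", cellIds(grid)))
  vals["Wheat", 1, ] <- c(20, 50)
  vals["Maize", 1, ] <- c(80, 0)
  cube <- new("HareaCube", values = vals, grid = grid, years = 2000L)
  nt <- matrix(c(10, 5), 1, 2, dimnames = list("2000", cellIds(grid)))
  surf <- cropNotillFraction(nt, cube)
  # 10 ha no-till split 2/8 over crops with areas 20/80
  cropArea <- surf@cropFraction[, 1, 1] * vals[, 1, 1]
  expect_equal(unname(cropArea), c(2, 8))
  expect_equal(sum(cropArea), 10)
  # single-crop cell: crop fraction equals the cell's no-till share
  expect_equal(unname(surf@cropFraction["Wheat", 1, 2]), 5 / 50)
  expect_equal(unname(surf@cropFraction["Maize", 1, 2]), 0)
  expect_true(all(surf@cropFraction >= 0 & surf@cropFraction <= 1))
})

test_that("placement shares implement the three-branch deep rule exactly", {
  v <- nfertVocabulary()
  nt <- array(c(0, 0.5, 1), c(1, 1, 3),
              dimnames = list("Wheat", "2000", c("g1", "g2", "g3")))
  surf <- new("NoTillSurface", notillArea = matrix(0, 1, 3),
              cellFraction = matrix(0, 1, 3), cropFraction = nt)
  pc <- placementShares(surf, v)
  # injected fertilizers are always deep
  expect_true(all(placementDeep(pc, "AA") == 1))
  expect_true(all(placementDeep(pc, "NS") == 1))
  expect_true(all(placementSurface(pc, "AA") == 0))
  # other synthetic fertilizer: 0.7 x NoTill
  expect_equal(unname(placementDeep(pc, "Urea")[1, 1, ]), c(0, 0.35, 0.7))
  # AN counts as "other fertilizer" unless the literal set is requested
  expect_equal(unname(placementDeep(pc, "AN")[1, 1, ]), c(0, 0.35, 0.7))
  pcLit <- placementShares(surf, v, literalInjected = TRUE)
  expect_true(all(placementDeep(pcLit, "AN") == 1))
  # manure/residues: 1 - NoTill (deep = 1 at NoTill = 0)
  expect_equal(unname(placementDeep(pc, "MA")[1, 1, ]), c(1, 0.5, 0))
  expect_equal(unname(placementDeep(pc, "CR")[1, 1, ]), c(1, 0.5, 0))
  # surface + deep = 1 exactly, for every type
  for (f in v$fertilizerTypes)
    expect_true(all(placementDeep(pc, f) + placementSurface(pc, f) == 1))
  # monotonicity in NoTill: non-decreasing for synthetic, non-increasing CR/MA
  expect_true(all(diff(placementDeep(pc, "Urea")[1, 1, ]) >= 0))
  expect_true(all(diff(placementDeep(pc, "MA")[1, 1, ]) <= 0))
})

test_that("allocated national no-till area matches its target on the world", {
  w <- getTinyWorld()
  run <- getTinyRun()
  pl <- run$placement
  ctry <- cellCountry(w@hierarchy)
  yc <- as.character(w@config$years)
  for (j in w@hierarchy@countries) {
    got <- rowSums(pl$surface@notillArea[, ctry == j, drop = FALSE])
    achievable <- rowSums((pl$potential * pl$probability)[, ctry == j,
                                                          drop = FALSE])
    want <- pmin(pl$national[j, yc], achievable)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})
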