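test_that("imputation is the identity on complete panels and never touches observed cells", {
  w <- getTinyWorld()
  full <- w@typeConsumptionPanel
  full$values[full$missingMask] <- 1
  full$missingMask[] <- FALSE
  expect_identical(imputeMissingConsumption(full, w@covariatePanel,
                                            w@hierarchy, seed = 4), full)

  imp <- imputeMissingConsumption(w@typeConsumptionPanel, w@covariatePanel,
                                  w@hierarchy, m = 3L, seed = 4)
  mask <- w@typeConsumptionPanel$missingMask
  expect_identical(imp$values[!mask], w@typeConsumptionPanel$values[!mask])
  expect_false(anyNA(imp$values))
  expect_true(all(imp$values >= 0))
  # deterministic under a fixed seed
  imp2 <- imputeMissingConsumption(w@typeConsumptionPanel, w@covariatePanel,
                                   w@hierarchy, m = 3L, seed = 4)
  expect_identical(imp, imp2)
})

test_that("bootstrap-EM imputation beats column-mean imputation under 20% MCAR", {
  w <- generateWorld(tinyWorldConfig(seed = 3, missingYearBlock = integer(),
                                     missingRate = 0))
  full <- w@typeConsumptionPanel
  blanked <- injectMissingness(full, yearBlock = integer(), rate = 0.2,
                               seed = 42)
  imp <- imputeMissingConsumption(blanked, w@covariatePanel, w@hierarchy,
                                  m = 5L, seed = 9)
  mask <- blanked$missingMask
  truth <- full$values[mask]
  rmse <- sqrt(mean((imp$values[mask] - truth)^2))
  colMean <- blanked$values
  for (f in dimnames(colMean)[[1]]) for (m in dimnames(colMean)[[2]]) {
    v <- colMean[f, m, ]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    colMean[f, m, ] <- v
  }
  rmse0 <- sqrt(mean((colMean[mask] - truth)^2))
  expect_lt(rmse, rmse0)
})

test_that("units with too few observations fall back to interpolation", {
  w <- getTinyWorld()
  panel <- w@typeConsumptionPanel
  # blank everything but two years in region R1
  keep <- c("1961", "2020")
  panel$values[, "R1", !dimnames(panel$values)[[3]] %in% keep] <- NA
  expect_warning(
    imp <- imputeMissingConsumption(panel, w@covariatePanel, w@hierarchy,
                                    seed = 1),
    "interpolation")
  expect_false(anyNA(imp$values[, "R1", ]))
  expect_identical(imp$values[, "R1", keep], panel$values[, "R1", keep])
})

test_that("type shares follow the two-branch rule and sum to one", {
  hier <- adminHierarchy(
    countries = "C01", counties = "C01_c1",
    countyCountry = c(C01_c1 = "C01"), membership = rep("C01_c1", 4),
    regions = c(C01 = "R1"))
  grid <- gridDefinition(2, 2, 1)
  v <- nfertVocabulary()
  namount <- array(c(50, 25, 25), c(3, 1, 1),
                   dimnames = list(c("SN", "MA", "CR"), "C01_c1", "2000"))
  vals <- array(0, c(11, 1, 1), dimnames = list(v$snTypes, "R1", "2000"))
  vals["Urea", , ] <- 60
  vals["AS", , ] <- 40
  panel <- list(values = vals, totalSn = matrix(100, 1, 1,
                                                dimnames = list("R1", "2000")),
                missingMask = array(FALSE, dim(vals)))
  shares <- computeTypeShares(panel, namount, hier, grid, v)
  cs <- shares@county[, 1, 1]
  # CR amount 25 of 100 total
  expect_equal(unname(cs["CR"]), 0.25)
  expect_equal(unname(cs["MA"]), 0.25)
  # urea: 60% of SN consumption times SN fraction 0.5
  expect_equal(unname(cs["Urea"]), 0.30)
  expect_equal(unname(cs["AS"]), 0.20)
  expect_equal(sum(cs), 1)
  # rasterized: every cell carries the county shares
  expect_equal(unname(shares@values["Urea", 1, ]), rep(0.30, 4))

  # zero consumption mix with positive SN routes mass to urea
  panel0 <- panel
  panel0$values[] <- 0
  expect_warning(sh0 <- computeTypeShares(panel0, namount, hier, grid, v),
                 "urea")
  expect_equal(unname(sh0@county["Urea", 1, 1]), 0.5)
  expect_equal(sum(sh0@county[, 1, 1]), 1)

  # idempotence: identical inputs give bit-identical results
  expect_identical(shares, computeTypeShares(panel, namount, hier, grid, v))
})

test_that("share sums are exactly one wherever the total amount is positive", {
  w <- getTinyWorld()
  run <- getTinyRun()
  total <- colSums(run$napp$postAmount)
  s <- colSums(run$shares@county)
  expect_lt(max(abs(s[total > 0] - 1)), 1e-9)
  expect_true(all(run$shares@values >= 0 & run$shares@values <= 1 + 1e-12))
  # noise-free recovery of true shares in fully observed years
  obs <- !apply(w@typeConsumptionPanel$missingMask, 3, any)
  gt <- w@groundTruth$typeShares
  expect_lt(max(abs(run$shares@county[, , obs] - gt[, , obs])), 1e-9)
})
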