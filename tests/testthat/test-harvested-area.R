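# Small hand-built scaffold shared by the unit examples below: one country,
# two counties, a 2x2 grid.
makeToy <- function() {
  grid <- gridDefinition(2, 2, 1)
  hier <- adminHierarchy(
    countries = "C01", counties = c("C01_c1", "C01_c2"),
    countyCountry = c(C01_c1 = "C01", C01_c2 = "C01"),
    membership = c("C01_c1", "C01_c1", "C01_c2", "C01_c2"),
    regions = c(C01 = "R1"))
  list(grid = grid, hier = hier)
}

test_that("reference-map extension applies the national ratio per county", {
  toy <- makeToy()
  yrs <- c("2000", "2001")
  ref <- matrix(c(100, 40), 1, 2, dimnames = list("Wheat", toy$hier@counties))
  national <- array(c(140, 210), c(1, 1, 2),
                    dimnames = list("Wheat", "C01", yrs))
  out <- extendHarvestedArea(ref, national, toy$hier)
  # y = 2000: ratio 1, output equals the reference map
  expect_equal(out[, , "2000"], ref[1, ])
  # ratio 150/100 per the national series
  expect_equal(unname(out["Wheat", "C01_c1", "2001"]), 150)
  expect_equal(unname(out["Wheat", "C01_c2", "2001"]), 60)
  # both counties share the same national factor
  expect_equal(out[, , "2001"] / out[, , "2000"], c(C01_c1 = 1.5, C01_c2 = 1.5))
})

test_that("zero reference-year national value falls back to a uniform split", {
  toy <- makeToy()
  national <- array(c(0, 80), c(1, 1, 2),
                    dimnames = list("Wheat", "C01", c("2000", "2001")))
  ref <- matrix(0, 1, 2, dimnames = list("Wheat", toy$hier@counties))
  expect_warning(out <- extendHarvestedArea(ref, national, toy$hier),
                 "uniform")
  expect_equal(unname(out["Wheat", , "2001"]), c(40, 40))
})

test_that("disintegration splits parent-era values by first-post-split shares", {
  yrs <- as.character(1990:1994)
  national <- array(NA_real_, c(1, 3, 5),
                    dimnames = list("Wheat", c("A", "B", "P"), yrs))
  national["Wheat", "P", c("1990", "1991")] <- c(100, 110)
  national["Wheat", "A", c("1992", "1993", "1994")] <- c(30, 33, 36)
  national["Wheat", "B", c("1992", "1993", "1994")] <- c(70, 77, 84)
  ev <- list(list(parent = "P", year = 1992L, successors = c("A", "B")))
  out <- handleDisintegration(national, ev)
  expect_false("P" %in% dimnames(out)[[2]])
  # parent-era totals split 30% / 70%
  expect_equal(unname(out["Wheat", "A", "1990"]), 30)
  expect_equal(unname(out["Wheat", "B", "1990"]), 70)
  expect_equal(unname(out["Wheat", "A", "1991"]), 33)
  # years >= split untouched
  expect_equal(unname(out["Wheat", "A", "1993"]), 33)
  expect_equal(unname(out["Wheat", "B", "1994"]), 84)

  # single successor inherits everything
  ev1 <- list(list(parent = "P", year = 1992L, successors = "B"))
  out1 <- handleDisintegration(national, ev1)
  expect_equal(unname(out1["Wheat", "B", "1990"]), 100)

  # all-zero successors: equal split with a warning
  nat0 <- national
  nat0["Wheat", c("A", "B"), "1992"] <- 0
  expect_warning(out0 <- handleDisintegration(nat0, ev), "equal")
  expect_equal(unname(out0["Wheat", "A", "1990"]), 50)
})

test_that("gridding follows the matching cropland layer and conserves counties", {
  toy <- makeToy()
  yrs <- "2000"
  county <- array(c(100, 50), c(2, 2, 1),
                  dimnames = list(c("Wheat", "Rice"), toy$hier@counties, yrs))
  county["Wheat", "C01_c2", 1] <- 80
  county["Rice", "C01_c1", 1] <- 60
  cropland <- list(
    upland = matrix(c(30, 70, 10, 0), 1, 4,
                    dimnames = list(yrs, cellIds(toy$grid))),
    rice = matrix(c(20, 20, 0, 5), 1, 4,
                  dimnames = list(yrs, cellIds(toy$grid))))
  cube <- disaggregateToGrid(county, cropland, toy$hier, toy$grid)
  # wheat 100 ha split 30/70 over county 1's cells
  expect_equal(unname(cube@values["Wheat", 1, 1:2]), c(30, 70))
  # rice uses the rice layer even where upland differs
  expect_equal(unname(cube@values["Rice", 1, 1:2]), c(30, 30))
  # single cropland cell takes the whole county value
  expect_equal(unname(cube@values["Wheat", 1, 3:4]), c(80, 0))
  # rice in county 2 has one rice cell
  expect_equal(unname(cube@values["Rice", 1, 3:4]), c(0, 50))
  # county sums preserved
  expect_equal(sum(cube@values["Wheat", 1, 1:2]), 100)
  expect_equal(sum(cube@values["Rice", 1, 3:4]), 50)
})

test_that("zero-cropland county with crop area spreads uniformly", {
  toy <- makeToy()
  yrs <- "2000"
  county <- array(c(0, 10), c(1, 2, 1),
                  dimnames = list("Wheat", toy$hier@counties, yrs))
  cropland <- list(
    upland = matrix(c(1, 1, 0, 0), 1, 4,
                    dimnames = list(yrs, cellIds(toy$grid))),
    rice = matrix(0, 1, 4, dimnames = list(yrs, cellIds(toy$grid))))
  expect_warning(cube <- disaggregateToGrid(county, cropland, toy$hier,
                                            toy$grid), "uniform")
  expect_equal(unname(cube@values["Wheat", 1, 3:4]), c(5, 5))
})

test_that("matching rescales to national totals and handles edge targets", {
  toy <- makeToy()
  yrs <- "2000"
  vals <- array(c(30, 30, 20, 10), c(1, 1, 4),
                dimnames = list("Wheat", yrs, cellIds(toy$grid)))
  cube <- new("HareaCube", values = vals, grid = toy$grid, years = 2000L)
  national <- array(99, c(1, 1, 1), dimnames = list("Wheat", "C01", yrs))
  out <- matchNationalTotals(cube, national, toy$hier)
  expect_equal(unname(out@values["Wheat", 1, ]), c(30, 30, 20, 10) * 1.1)
  # already matching: unchanged
  national[] <- 90
  expect_equal(matchNationalTotals(cube, national, toy$hier)@values,
               cube@values)
  # zero target zeroes the cells
  national[] <- 0
  expect_true(all(matchNationalTotals(cube, national, toy$hier)@values == 0))
  # zero cube with positive target spreads uniformly
  cube0 <- new("HareaCube", values = vals * 0, grid = toy$grid, years = 2000L)
  national[] <- 8
  out0 <- matchNationalTotals(cube0, national, toy$hier)
  expect_equal(unname(out0@values["Wheat", 1, ]), rep(2, 4))
})

test_that("mass conservation and linearity hold on the synthetic world", {
  w <- getTinyWorld()
  res <- buildHarvestedArea(w)
  yc <- as.character(w@config$years)
  ctry <- cellCountry(w@hierarchy)
  for (j in w@hierarchy@countries) {
    sums <- rowSums(res$cube@values[, , ctry == j, drop = FALSE], dims = 2L)
    want <- res$national[, j, yc]
    err <- abs(sums - want) / pmax(abs(want), 1)
    expect_lt(max(err), 1e-9)
  }
  # doubling the national series doubles the gridded cube
  w2 <- w
  w2@countryHareaSeries <- w@countryHareaSeries * 2
  res2 <- buildHarvestedArea(w2)
  expect_equal(res2$cube@values, res$cube@values * 2, tolerance = 1e-12)
  # noise-free recovery of the true county areas
  gt <- w@groundTruth$countyHarea
  err <- abs(res$county - gt) / pmax(gt, 1e-9)
  expect_lt(max(err[gt > 0]), 1e-12)
})
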