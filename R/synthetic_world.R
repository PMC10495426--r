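# Synthetic world: a small, fully self-consistent planet whose ground-truth
# crop rates, type mixes and no-till adoption are known, so every pipeline
# stage can be tested offline against exact expectations.

#' Configuration of a synthetic world
#'
#' Defaults are the study conditions of the reconstruction: the 1961-2020
#' period, a year-2000 reference epoch, five FUBC anchor years, an IFA type
#' panel missing for all of 1962-1972 plus 6 percent at random, a prior
#' county-level SN product biased 12 percent low against national statistics,
#' and one political disintegration so successor handling is exercised.
#'
#' @param seed integer seed; identical seeds give bit-identical worlds.
#' @param years inclusive year range; must contain 2000, 2014 and at least two
#'   FUBC anchor years (2006, 2007, 2010, 2014, 2018).
#' @param nCountries,countiesPerCountry sizes of the administrative scaffold.
#' @param nRows,nCols,resolution grid shape (degrees per cell).
#' @param noiseSd standard deviation of the multiplicative log-normal noise
#'   applied to statistical panels; 0 gives the exact regime used by the
#'   recovery tests.
#' @param missingYearBlock years blanked in the type-consumption panel for all
#'   reporting units.
#' @param missingRate additional missing-completely-at-random fraction in the
#'   type-consumption panel.
#' @param wangSnBias multiplicative bias of the prior county SN product
#'   relative to national statistics (0.88 = 12 percent low).
#' @param croplandUseFraction fraction of national SN applied to cropland (as
#'   opposed to pasture); scalar or named per-country vector.
#' @param notillAsym asymptote of the true national no-till adoption curve.
#' @param disintegrationYear split year of the generated disintegration event.
#' @return A validated configuration list of class `WorldConfig`.
#' @export
worldConfig <- function(seed = 1L, years = 1961:2020, nCountries = 4L,
                        countiesPerCountry = 3L, nRows = 24L, nCols = 48L,
                        resolution = 7.5, noiseSd = 0.05,
                        missingYearBlock = 1962:1972, missingRate = 0.06,
                        wangSnBias = 0.88, croplandUseFraction = 1,
                        notillAsym = 0.12, disintegrationYear = 1993L) {
  cfg <- list(seed = as.integer(seed), years = as.integer(years),
              nCountries = as.integer(nCountries),
              countiesPerCountry = as.integer(countiesPerCountry),
              nRows = as.integer(nRows), nCols = as.integer(nCols),
              resolution = resolution, noiseSd = noiseSd,
              missingYearBlock = as.integer(missingYearBlock),
              missingRate = missingRate, wangSnBias = wangSnBias,
              croplandUseFraction = croplandUseFraction,
              notillAsym = notillAsym,
              disintegrationYear = as.integer(disintegrationYear))
  validateWorldConfig(cfg)
  cfg
}

fubcAnchorYears <- function() c(2006L, 2007L, 2010L, 2014L, 2018L)

validateWorldConfig <- function(cfg) {
  yrs <- cfg$years
  if (length(yrs) < 2L || any(diff(yrs) != 1L))
    stop("years must be a contiguous, increasing range", call. = FALSE)
  if (cfg$nCountries < 1L || cfg$countiesPerCountry < 1L)
    stop("need at least one country and one county per country", call. = FALSE)
  if (!(2000L %in% yrs) || !(2014L %in% yrs))
    stop("years must include the 2000 reference year and 2014", call. = FALSE)
  if (sum(fubcAnchorYears() %in% yrs) < 2L)
    stop("years must span at least two FUBC anchor years", call. = FALSE)
  if (cfg$noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  if (cfg$missingRate < 0 || cfg$missingRate > 1)
    stop("missingRate must lie in [0, 1]", call. = FALSE)
  if (cfg$wangSnBias <= 0) stop("wangSnBias must be > 0", call. = FALSE)
  if (any(cfg$croplandUseFraction <= 0 | cfg$croplandUseFraction > 1))
    stop("croplandUseFraction must lie in (0, 1]", call. = FALSE)
  if (cfg$notillAsym < 0 || cfg$notillAsym > 1)
    stop("notillAsym must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

# even split of n items into k contiguous chunks
chunkIndex <- function(n, k) sort(rep_len(seq_len(k), n))

lognoise <- function(n, sd) {
  if (sd <= 0) rep(1, n) else exp(stats::rnorm(n, 0, sd))
}

#' Generate a synthetic world
#'
#' Builds the complete input bundle of the reconstruction from a single
#' ground truth: county harvested areas follow fixed within-country shares
#' times national growth curves (so the national-ratio extension is exact);
#' class amounts follow county year-2000 amounts times country-level growth
#' (so the constant-ratio assumption holds by construction); the prior SN
#' panel is biased by `wangSnBias`; FUBC tables, the IFA type panel, the
#' year-2000 reference maps and the no-till drivers are all derived from that
#' same truth. With `noiseSd = 0` every panel re-aggregates the truth to
#' machine precision.
#'
#' @param config a configuration from [worldConfig()].
#' @return A [SyntheticWorld-class] object.
#' @examples
#' w <- generateWorld(worldConfig(seed = 7, nRows = 12, nCols = 12,
#'                                nCountries = 2, countiesPerCountry = 2))
#' w
#' @export
generateWorld <- function(config) {
  validateWorldConfig(config)
  set.seed(config$seed)
  vocab <- nfertVocabulary()
  crops <- vocab$cropGroups
  classes <- vocab$classes
  years <- config$years
  ny <- length(years)
  yc <- as.character(years)

  grid <- gridDefinition(config$nRows, config$nCols, config$resolution)
  ncell <- nCells(grid)

  ## ---- administrative scaffold -------------------------------------------
  nC <- config$nCountries
  countries <- sprintf("C%02d", seq_len(nC))
  counties <- as.vector(vapply(countries, function(j)
    sprintf("%s_c%d", j, seq_len(config$countiesPerCountry)),
    character(config$countiesPerCountry)))
  countyCountry <- stats::setNames(rep(countries,
                                       each = config$countiesPerCountry),
                                   counties)
  colCountry <- chunkIndex(config$nCols, nC)          # column block per country
  rowCounty <- chunkIndex(config$nRows, config$countiesPerCountry)
  cellRow <- rep(seq_len(config$nRows), each = config$nCols)
  cellCol <- rep(seq_len(config$nCols), times = config$nRows)
  membership <- sprintf("%s_c%d", countries[colCountry[cellCol]],
                        rowCounty[cellRow])
  regions <- stats::setNames(
    ifelse(seq_len(nC) <= ceiling(nC / 2), "R1", "R2"), countries)
  events <- list()
  splitYear <- config$disintegrationYear
  if (nC >= 2L && splitYear > min(years) && splitYear <= max(years))
    events <- list(list(parent = "P01", year = splitYear,
                        successors = countries[1:2]))
  hierarchy <- adminHierarchy(countries, counties, countyCountry, membership,
                              regions, events)
  cellsOf <- countyCells(hierarchy)

  ## ---- cropland cube ------------------------------------------------------
  areaHa <- cellAreaHa(grid)
  uplandShare <- stats::rbeta(ncell, 2, 5)            # cropland share of cell
  riceShareCounty <- stats::setNames(stats::runif(length(counties), 0, 0.4),
                                     counties)
  riceShareCell <- numeric(ncell)
  for (i in counties) riceShareCell[cellsOf[[i]]] <- riceShareCounty[i]
  uplandBase <- areaHa * uplandShare * (1 - riceShareCell)
  riceBase <- areaHa * uplandShare * riceShareCell
  cgRate <- stats::setNames(stats::runif(nC, 0, 0.005), countries)
  cellCtry <- cellCountry(hierarchy)
  croplandYearKey <- function(y) {
    if (y > 2017L) 2017L else if (y >= 2000L) y else 10L * (y %/% 10L)
  }
  growY <- vapply(years, function(y)
    (1 + cgRate)^(croplandYearKey(y) - 2000L), numeric(nC))  # country x year
  cellGrow <- growY[match(cellCtry, countries), , drop = FALSE] # cell x year
  upland <- t(cellGrow * uplandBase)                  # year x cell
  rice <- t(cellGrow * riceBase)
  dimnames(upland) <- dimnames(rice) <- list(yc, cellIds(grid))

  ## ---- ground-truth harvested areas --------------------------------------
  # national year-2000 areas per crop; shares over counties fixed in time
  cropWeight <- stats::setNames(stats::rgamma(length(crops), shape = 1.2),
                                crops)
  cropWeight[c("Wheat", "Maize", "Rice")] <-
    cropWeight[c("Wheat", "Maize", "Rice")] + 2
  H2000 <- outer(cropWeight / sum(cropWeight), vapply(countries, function(j)
    sum(upland["2000", cellCtry == j]) + sum(rice["2000", cellCtry == j]),
    numeric(1)) * 0.9)                                # crop x country
  gamma <- matrix(stats::runif(length(crops) * nC, -0.005, 0.02),
                  length(crops), nC, dimnames = list(crops, countries))
  if (length(events)) gamma[, 2] <- gamma[, 1]        # successors share growth
  natH <- array(0, c(length(crops), nC, ny),
                dimnames = list(crops, countries, yc))
  for (k in seq_len(ny))
    natH[, , k] <- H2000 * (1 + gamma)^(years[k] - 2000L)

  w <- matrix(0, length(crops), length(counties),
              dimnames = list(crops, counties))       # county shares per crop
  for (j in countries) {
    cnt <- countiesOf(hierarchy, j)
    up2000 <- vapply(cnt, function(i) sum(upland["2000", cellsOf[[i]]]),
                     numeric(1))
    ri2000 <- vapply(cnt, function(i) sum(rice["2000", cellsOf[[i]]]),
                     numeric(1))
    for (cro in crops) {
      base <- if (cro == "Rice") ri2000 else
        up2000 * stats::runif(length(cnt), 0.5, 1.5)
      w[cro, cnt] <- if (sum(base) > 0) base / sum(base) else
        rep(1 / length(cnt), length(cnt))
    }
  }
  trueHarea <- array(0, c(length(crops), length(counties), ny),
                     dimnames = list(crops, counties, yc))
  for (i in counties)
    trueHarea[, i, ] <- natH[, countyCountry[i], ] * w[, i]

  ## ---- year-2000 reference rate map + true class amounts ------------------
  snBase <- stats::setNames(stats::runif(length(crops), 30, 150), crops)
  maMul <- stats::runif(length(crops), 0.15, 0.5)
  crMul <- stats::runif(length(crops), 0.05, 0.2)
  refRate <- array(0, c(length(crops), 3L, length(counties)),
                   dimnames = list(crops, classes, counties))
  for (i in counties) {
    mult <- stats::runif(length(crops), 0.7, 1.3)
    refRate[, "SN", i] <- snBase * mult
    refRate[, "MA", i] <- snBase * maMul * mult
    refRate[, "CR", i] <- snBase * crMul * mult
  }

  a2000 <- vapply(counties, function(i)
    colSums(refRate[, , i] * trueHarea[, i, "2000"]), numeric(3L)) # class x cty
  # country-level growth per class, logistic uptake normalized at 2000
  g <- array(0, c(3L, nC, ny), dimnames = list(classes, countries, yc))
  for (f in classes) for (jx in seq_len(nC)) {
    t0 <- stats::runif(1, 1975, 1995); tau <- stats::runif(1, 6, 12)
    raw <- 0.15 + 0.85 * stats::plogis((years - t0) / tau)
    g[f, jx, ] <- raw / raw[years == 2000L]
  }
  trueAmount <- array(0, c(3L, length(counties), ny),
                      dimnames = list(classes, counties, yc))
  for (i in counties)
    trueAmount[, i, ] <- a2000[, i] * g[, countyCountry[i], ]

  # true rates under the constant-ratio assumption
  trueRates <- array(0, c(length(crops), 3L, length(counties), ny),
                     dimnames = list(crops, classes, counties, yc))
  for (i in counties) for (f in classes) {
    denom <- colSums(refRate[, f, i] * trueHarea[, i, ])     # per year
    fac <- ifelse(denom > 0, trueAmount[f, i, ] / denom, 0)
    trueRates[, f, i, ] <- outer(refRate[, f, i], fac)
  }

  ## ---- statistical panels (with optional noise) ---------------------------
  noisy <- function(x) x * array(lognoise(length(x), config$noiseSd), dim(x))

  countryHareaSeries <- array(NA_real_, c(length(crops), nC, ny),
                              dimnames = list(crops, countries, yc))
  for (j in countries) countryHareaSeries[, j, ] <- noisy(natH[, j, ])
  if (length(events)) {
    ev <- events[[1]]
    pre <- years < ev$year
    parent <- apply(countryHareaSeries[, ev$successors, pre, drop = FALSE],
                    c(1, 3), sum)
    countryHareaSeries[, ev$successors, pre] <- NA_real_
    withParent <- array(NA_real_, c(length(crops), nC + 1L, ny),
                        dimnames = list(crops, c(countries, ev$parent), yc))
    withParent[, countries, ] <- countryHareaSeries
    withParent[, ev$parent, pre] <- parent
    countryHareaSeries <- withParent
  }

  refHareaMap <- trueHarea[, , "2000"]

  wangYears <- yc[years <= 2014L]
  prior <- trueAmount[, , wangYears, drop = FALSE]
  prior["SN", , ] <- prior["SN", , ] * config$wangSnBias
  prior <- noisy(prior)

  useFrac <- rep_len(config$croplandUseFraction, nC)
  names(useFrac) <- countries
  if (!is.null(names(config$croplandUseFraction)))
    useFrac[names(config$croplandUseFraction)] <- config$croplandUseFraction
  faoSeries <- array(0, c(3L, nC, ny), dimnames = list(classes, countries, yc))
  for (j in countries) {
    tot <- apply(trueAmount[, countiesOf(hierarchy, j), , drop = FALSE],
                 c(1, 3), sum)
    tot["SN", ] <- tot["SN", ] / useFrac[j]   # FAO SN includes pasture uses
    faoSeries[, j, ] <- noisy(tot)
  }

  ## ---- FUBC tables ---------------------------------------------------------
  cro2 <- vocab$fubcCropGroups
  groupAmount <- function(y) {
    # cro2 x country SN amounts implied by the truth in year y
    amt <- trueRates[, "SN", , as.character(y)] *
      trueHarea[, , as.character(y)]                  # crop x county
    byCountry <- t(rowsum(t(amt), countyCountry[colnames(amt)]))
    out <- rowsum(byCountry, vocab$cropToFubc[rownames(byCountry)])
    out[cro2, countries, drop = FALSE]
  }
  anchors <- intersect(fubcAnchorYears(), years)
  fubcAnchors <- array(0, c(length(cro2), nC, length(anchors)),
                       dimnames = list(cro2, countries, as.character(anchors)))
  for (y in anchors)
    fubcAnchors[, , as.character(y)] <- noisy(groupAmount(y))
  histYears <- intersect(1978:2001, years)
  fubcHistoric <- array(0, c(length(cro2), nC, length(histYears)),
                        dimnames = list(cro2, countries,
                                        as.character(histYears)))
  for (y in histYears)
    fubcHistoric[, , as.character(y)] <- noisy(groupAmount(y))

  ## ---- IFA fertilizer-type panel ------------------------------------------
  snTypes <- vocab$snTypes
  regs <- sort(unique(regions))
  w0 <- matrix(stats::runif(length(snTypes) * length(regs), 0.2, 1.5),
               length(snTypes), length(regs),
               dimnames = list(snTypes, regs))
  w0["Urea", ] <- w0["Urea", ] + 5                   # urea-dominant mixes
  drift <- matrix(stats::rnorm(length(snTypes) * length(regs), 0, 0.01),
                  length(snTypes), length(regs))
  trueMix <- array(0, c(length(snTypes), length(regs), ny),
                   dimnames = list(snTypes, regs, yc))
  for (k in seq_len(ny)) {
    wk <- exp(log(w0) + drift * (years[k] - 1990L))
    trueMix[, , k] <- sweep(wk, 2, colSums(wk), "/")
  }
  regionalSn <- vapply(regs, function(m) {
    js <- countries[regions[countries] == m]
    cnt <- unlist(lapply(js, countiesOf, hierarchy = hierarchy))
    colSums(matrix(trueAmount["SN", cnt, ], ncol = ny))
  }, numeric(ny))                                    # year x region
  typeValues <- array(0, c(length(snTypes), length(regs), ny),
                      dimnames = list(snTypes, regs, yc))
  for (m in regs)
    typeValues[, m, ] <- noisy(trueMix[, m, ] *
                                 rep(regionalSn[, m], each = length(snTypes)))
  totalSn <- apply(typeValues, c(2, 3), sum)
  typePanel <- list(values = typeValues, totalSn = totalSn,
                    missingMask = array(FALSE, dim(typeValues),
                                        dimnames = dimnames(typeValues)))
  typePanel <- injectMissingness(typePanel,
                                 yearBlock = config$missingYearBlock,
                                 rate = config$missingRate)

  ## ---- covariates and no-till drivers -------------------------------------
  gdp <- pop <- rural <- matrix(0, nC, ny, dimnames = list(countries, yc))
  for (jx in seq_len(nC)) {
    gdp[jx, ] <- stats::runif(1, 1e9, 5e10) *
      (1 + stats::runif(1, 0.01, 0.05))^(years - min(years))
    pop[jx, ] <- stats::runif(1, 1e6, 1e8) *
      (1 + stats::runif(1, 0, 0.02))^(years - min(years))
    share <- seq(stats::runif(1, 0.6, 0.8), stats::runif(1, 0.2, 0.4),
                 length.out = ny)
    rural[jx, ] <- pop[jx, ] * share
  }
  croplandArea <- rowsum(t(upland + rice), cellCtry)[countries, ,
                                                     drop = FALSE]

  income <- stats::setNames(rep(c("high", "low"), length.out = nC), countries)
  censusCountries <- countries[max(1L, nC - 1L):nC]
  fieldSize <- sample(1:4, ncell, replace = TRUE,
                      prob = c(0.2, 0.3, 0.3, 0.2))
  erosion <- stats::runif(ncell, 0.1, 10)
  aridity <- stats::runif(ncell, 0.2, 2)
  rainfed <- stats::runif(ncell, 0.5, 1)

  cpc <- croplandArea / rural
  lcpc <- log(cpc)
  mid <- stats::median(lcpc[is.finite(lcpc)])
  notillFrac <- config$notillAsym * stats::plogis((lcpc - mid) / 0.5)
  notillNational <- notillFrac * croplandArea        # country x year
  censusRanges <- list(2000:2016, 1989:2008)
  censusNotill <- list()
  for (k in seq_along(censusCountries)) {
    j <- censusCountries[k]
    cyrs <- intersect(censusRanges[[min(k, length(censusRanges))]], years)
    cnt <- countiesOf(hierarchy, j)
    shareC <- vapply(cnt, function(i)
      sum(upland["2000", cellsOf[[i]]] + rice["2000", cellsOf[[i]]]),
      numeric(1))
    shareC <- shareC / sum(shareC)
    censusNotill[[j]] <- outer(shareC,
                               notillNational[j, as.character(cyrs)])
    dimnames(censusNotill[[j]]) <- list(cnt, as.character(cyrs))
  }

  ## ---- ground-truth type shares -------------------------------------------
  trueShares <- array(0, c(13L, length(counties), ny),
                      dimnames = list(vocab$fertilizerTypes, counties, yc))
  totalAmt <- apply(trueAmount, c(2, 3), sum)
  pos <- totalAmt > 0
  for (f in c("MA", "CR")) {
    sh <- trueAmount[f, , ] / ifelse(pos, totalAmt, 1)
    sh[!pos] <- 0
    trueShares[f, , ] <- sh
  }
  snShare <- trueAmount["SN", , ] / ifelse(pos, totalAmt, 1)
  for (i in counties) {
    m <- regions[countyCountry[i]]
    trueShares[snTypes, i, ] <- trueMix[, m, ] *
      rep(ifelse(pos[i, ], snShare[i, ], 0), each = length(snTypes))
  }

  new("SyntheticWorld",
      vocabulary = vocab, grid = grid, hierarchy = hierarchy, config = config,
      referenceHareaMap = refHareaMap,
      countryHareaSeries = countryHareaSeries,
      croplandCube = list(rice = rice, upland = upland),
      priorNamountPanel = prior, faoNamountSeries = faoSeries,
      referenceRateMap = refRate,
      fubcTables = list(anchors = fubcAnchors, historic = fubcHistoric),
      typeConsumptionPanel = typePanel,
      covariatePanel = list(gdp = gdp, population = pop,
                            ruralPopulation = rural,
                            croplandArea = croplandArea,
                            croplandUseFraction = useFrac),
      notillDrivers = list(fieldSize = fieldSize, erosion = erosion,
                           aridity = aridity, rainfedFraction = rainfed,
                           incomeClass = income,
                           censusCountries = censusCountries,
                           censusNotill = censusNotill),
      groundTruth = list(countyHarea = trueHarea, natHarea = natH,
                         amounts = trueAmount, rates = trueRates,
                         typeShares = trueShares, typeMix = trueMix,
                         notillNational = notillNational,
                         notillFraction = notillFrac))
}

#' Blank cells of a type-consumption panel
#'
#' Reproduces the missingness structure of fertilizer-type consumption
#' statistics: a whole block of years (1962-1972 by default) is blank for all
#' reporting units, plus an additional completely-at-random fraction. Totals
#' (`totalSn`) stay observed, as in the source statistics. A logical mask of
#' blanked cells is retained for imputation scoring.
#'
#' @param panel a list with `values` (type x region x year), `totalSn` and
#'   `missingMask`, as in a [SyntheticWorld-class].
#' @param yearBlock integer years to blank for all units (may be empty).
#' @param rate additional MCAR missing fraction among remaining cells.
#' @param seed optional seed for the MCAR draw (the generator supplies its
#'   own stream).
#' @return The panel with `values` blanked to `NA` and `missingMask` updated.
#' @export
injectMissingness <- function(panel, yearBlock = 1962:1972, rate = 0.06,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- panel$values
  mask <- array(FALSE, dim(vals), dimnames = dimnames(vals))
  yrs <- dimnames(vals)[[3]]
  blockIdx <- yrs %in% as.character(yearBlock)
  if (any(blockIdx)) mask[, , blockIdx] <- TRUE
  if (rate > 0) {
    eligible <- which(!mask)
    hit <- eligible[stats::runif(length(eligible)) < rate]
    mask[hit] <- TRUE
  }
  vals[mask] <- NA_real_
  panel$values <- vals
  panel$missingMask <- mask
  panel
}
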