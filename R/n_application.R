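# Crop-specific N application rates by class (SN/MA/CR): extend the county
# prior to the present with national ratios, correct SN to national
# statistics, split county amounts across crops under the constant-ratio
# assumption, calibrate SN against crop-group survey consumption, rasterize.

#' Extend a county N-amount panel beyond its last year by national ratios
#'
#' For years after the prior's last year (2014), county amounts follow the
#' national change of the corresponding class:
#' `NamountW[f, y, i] = NamountW[f, 2014, i] * NamountFAO[f, y, j] / NamountFAO[f, 2014, j]`.
#' Years up to 2014 are untouched. A zero national value in 2014 with later
#' positive values is spread uniformly over the country's counties (flagged).
#'
#' @param prior numeric array `class x county x year` (kg N), covering the
#'   years up to `pivotYear`.
#' @param fao numeric array `class x country x year` (kg N), full period.
#' @param hierarchy an [AdminHierarchy-class].
#' @param pivotYear last year of the prior (2014).
#' @return numeric array `class x county x year` over the full FAO period.
#' @export
extendNAmount <- function(prior, fao, hierarchy, pivotYear = 2014L) {
  classes <- dimnames(prior)[[1]]
  counties <- dimnames(prior)[[2]]
  yrs <- as.integer(dimnames(fao)[[3]])
  yc <- as.character(yrs)
  out <- array(0, c(length(classes), length(counties), length(yrs)),
               dimnames = list(classes, counties, yc))
  keep <- intersect(dimnames(prior)[[3]], yc)
  out[, , keep] <- prior[, , keep]
  late <- yc[yrs > pivotYear]
  if (!length(late)) return(out)
  pv <- as.character(pivotYear)
  for (j in hierarchy@countries) {
    cnt <- intersect(countiesOf(hierarchy, j), counties)
    if (!length(cnt)) next
    for (f in classes) {
      ref <- fao[f, j, pv]
      if (is.finite(ref) && ref > 0) {
        ratio <- fao[f, j, late] / ref
        out[f, cnt, late] <- outer(prior[f, cnt, pv], ratio)
      } else if (any(fao[f, j, late] > 0, na.rm = TRUE)) {
        warning("zero ", pv, " national ", f, " amount for ", j,
                "; spreading later years uniformly over counties",
                call. = FALSE)
        out[f, cnt, late] <- matrix(rep(fao[f, j, late] / length(cnt),
                                        each = length(cnt)),
                                    nrow = length(cnt))
      }
    }
  }
  out
}

#' Correct county SN amounts to the national statistical series
#'
#' County synthetic-N amounts are rescaled by the country factor
#' `NamountFAO[SN, y, j] / sum_i NamountW[SN, y, i]`; manure and crop-residue
#' amounts pass through unchanged. A pasture correction can be applied first:
#' the national SN series is multiplied by the per-country fraction of
#' fertilizer use that goes to cropland.
#'
#' @param panel numeric array `class x county x year` (extended, see
#'   [extendNAmount()]).
#' @param fao numeric array `class x country x year`.
#' @param hierarchy an [AdminHierarchy-class].
#' @param croplandUseFraction scalar or named per-country vector in (0, 1];
#'   fraction of national SN applied to cropland.
#' @return The corrected `class x county x year` array; per country-year its
#'   SN sum equals the (cropland-use corrected) national SN exactly.
#' @export
correctSnToNational <- function(panel, fao, hierarchy,
                                croplandUseFraction = 1) {
  counties <- dimnames(panel)[[2]]
  yc <- dimnames(panel)[[3]]
  frac <- rep_len(1, length(hierarchy@countries))
  names(frac) <- hierarchy@countries
  if (is.null(names(croplandUseFraction))) {
    frac[] <- croplandUseFraction
  } else frac[names(croplandUseFraction)] <- croplandUseFraction
  for (j in hierarchy@countries) {
    cnt <- intersect(countiesOf(hierarchy, j), counties)
    if (!length(cnt)) next
    target <- fao["SN", j, yc] * frac[j]
    target[is.na(target)] <- 0
    have <- colSums(matrix(panel["SN", cnt, yc], ncol = length(yc)))
    fac <- ifelse(have > 0, target / have, NA_real_)
    bad <- is.na(fac) & target > 0
    fac[is.na(fac)] <- 0
    panel["SN", cnt, ] <- panel["SN", cnt, ] *
      rep(fac, each = length(cnt))
    if (any(bad)) {
      warning("zero county SN sum with positive national SN for ", j,
              "; spreading uniformly over counties", call. = FALSE)
      panel["SN", cnt, bad] <- matrix(rep(target[bad] / length(cnt),
                                          each = length(cnt)),
                                      nrow = length(cnt))
    }
  }
  panel
}

#' Split county class amounts across crops under the constant-ratio assumption
#'
#' All crops in a county change their rate by the same factor over time:
#' `Nrate[cro, f, y, i] = refRate[cro, f, i] * Namount[f, y, i] /
#' sum_cro(refRate[cro, f, i] * Harea[cro, y, i])`, which conserves the county
#' class amount exactly. A zero denominator with a positive amount leaves the
#' rates at zero and flags the amount as unallocatable.
#'
#' @param namount numeric array `class x county x year` (kg N), corrected.
#' @param refRate numeric array `crop x class x county` (kg N/ha), year-2000
#'   reference rates.
#' @param hareaCounty numeric array `crop x county x year` (ha).
#' @return numeric array `crop x class x county x year` of rates (kg N/ha).
#' @export
scaleCropRates <- function(namount, refRate, hareaCounty) {
  crops <- dimnames(refRate)[[1]]
  classes <- dimnames(refRate)[[2]]
  counties <- dimnames(refRate)[[3]]
  yc <- dimnames(namount)[[3]]
  rates <- array(0, c(length(crops), length(classes), length(counties),
                      length(yc)),
                 dimnames = list(crops, classes, counties, yc))
  unallocatable <- 0
  for (i in counties) for (f in classes) {
    h <- matrix(hareaCounty[, i, yc], nrow = length(crops))
    denom <- colSums(refRate[, f, i] * h)
    amt <- namount[f, i, yc]
    fac <- ifelse(denom > 0, amt / denom, 0)
    unallocatable <- unallocatable + sum(amt[denom <= 0])
    rates[, f, i, ] <- outer(refRate[, f, i], fac)
  }
  if (unallocatable > 0)
    warning(sprintf("%.4g kg N unallocatable (zero reference rate-area denominator)",
                    unallocatable), call. = FALSE)
  rates
}

#' FUBC reference year of a calendar year
#'
#' The piecewise map used for crop-group calibration: 2003-2006 -> 2006,
#' 2007-2008 -> 2007, 2009-2012 -> 2010, 2013-2016 -> 2014, >= 2017 -> 2018.
#' Years before 2003 are not calibrated and return `NA`.
#'
#' @param y integer vector of years.
#' @return integer vector of anchor years (`NA` before 2003).
#' @examples
#' fubcReferenceYear(c(1999, 2005, 2011, 2020))
#' @export
fubcReferenceYear <- function(y) {
  y <- as.integer(y)
  out <- rep(NA_integer_, length(y))
  out[y >= 2003L & y <= 2006L] <- 2006L
  out[y >= 2007L & y <= 2008L] <- 2007L
  out[y >= 2009L & y <= 2012L] <- 2010L
  out[y >= 2013L & y <= 2016L] <- 2014L
  out[y >= 2017L] <- 2018L
  out
}

#' Calibrate SN rates to crop-group survey consumption
#'
#' For every year from 2003 on, synthetic-N rates are multiplied, per country
#' and FUBC crop group, by the factor
#' `NconFUBC[cro2, y0, j] / sum_{cro in cro2, i in j}(rate[cro, SN, y0, i] *
#' Harea[cro, y0, i])`, where `y0` is the anchor year of `y` (see
#' [fubcReferenceYear()]). Factors are computed once from pre-calibration
#' rates; at anchor years the calibrated group amounts equal the survey
#' values exactly. MA and CR rates pass through. Groups whose denominator is
#' zero while the survey value is positive are skipped with a warning.
#'
#' @param rates numeric array `crop x class x county x year`.
#' @param hareaCounty numeric array `crop x county x year` (ha).
#' @param fubc list with `anchors`: numeric array `cro2 x country x anchorYear`
#'   (kg N).
#' @param vocabulary the vocabulary list (crop -> FUBC group map).
#' @param hierarchy an [AdminHierarchy-class].
#' @return The calibrated rates array.
#' @export
calibrateToFubc <- function(rates, hareaCounty, fubc, vocabulary, hierarchy) {
  yrs <- as.integer(dimnames(rates)[[4]])
  y0 <- fubcReferenceYear(yrs)
  anchors <- dimnames(fubc$anchors)[[3]]
  y0[!as.character(y0) %in% anchors] <- NA_integer_
  crops <- dimnames(rates)[[1]]
  for (j in intersect(hierarchy@countries, dimnames(fubc$anchors)[[2]])) {
    cnt <- intersect(countiesOf(hierarchy, j), dimnames(rates)[[3]])
    if (!length(cnt)) next
    for (a in unique(stats::na.omit(y0))) {
      ac <- as.character(a)
      amt <- matrix(rates[, "SN", cnt, ac], nrow = length(crops)) *
        matrix(hareaCounty[, cnt, ac], nrow = length(crops))
      groupAmt <- rowsum(rowSums(amt), vocabulary$cropToFubc[crops])
      target <- fubc$anchors[, j, ac]
      ys <- as.character(yrs[which(!is.na(y0) & y0 == a)])
      for (g in dimnames(fubc$anchors)[[1]]) {
        denom <- if (g %in% rownames(groupAmt)) groupAmt[g, 1] else 0
        if (denom <= 0) {
          if (isTRUE(target[g] > 0))
            warning("zero pre-calibration amount for group '", g, "' in ", j,
                    " at anchor ", ac, "; group skipped", call. = FALSE)
          next
        }
        fac <- target[g] / denom
        members <- crops[vocabulary$cropToFubc[crops] == g]
        rates[members, "SN", cnt, ys] <- rates[members, "SN", cnt, ys] * fac
      }
    }
  }
  rates
}

#' Rasterize county rates to the grid
#'
#' Every cell of a county carries that county's rate; cells without a county
#' get rate 0.
#'
#' @param rates numeric array `crop x class x county x year`.
#' @param hierarchy an [AdminHierarchy-class].
#' @param grid the [GridDefinition-class].
#' @return An [NRateCube-class].
#' @export
rasterizeRates <- function(rates, hierarchy, grid) {
  d <- dim(rates)
  yrs <- dimnames(rates)[[4]]
  vals <- array(0, c(d[1], d[2], d[4], nCells(grid)),
                dimnames = list(dimnames(rates)[[1]], dimnames(rates)[[2]],
                                yrs, cellIds(grid)))
  cellsOf <- countyCells(hierarchy)
  for (i in dimnames(rates)[[3]]) {
    cells <- cellsOf[[i]]
    if (!length(cells)) next
    vals[, , , cells] <- rates[, , i, ]               # recycled over cells
  }
  new("NRateCube", byClass = vals, grid = grid, years = as.integer(yrs))
}

#' Run the N-amount / rate stage on a synthetic world
#'
#' Extension to the full period, SN correction to national statistics (with
#' the cropland-use fraction), constant-ratio crop split, FUBC calibration,
#' and rasterization.
#'
#' @param world a [SyntheticWorld-class].
#' @param hareaCounty numeric array `crop x county x year` from
#'   [buildHarvestedArea()].
#' @param calibrate logical; apply the FUBC calibration (default TRUE).
#' @return list with `namount` (class x county x year), `ratesPreFubc`,
#'   `rates` (crop x class x county x year) and the [NRateCube-class] `cube`.
#' @export
buildNApplication <- function(world, hareaCounty, calibrate = TRUE) {
  ext <- extendNAmount(world@priorNamountPanel, world@faoNamountSeries,
                       world@hierarchy)
  namount <- correctSnToNational(ext, world@faoNamountSeries, world@hierarchy,
                                 world@covariatePanel$croplandUseFraction)
  ratesPre <- scaleCropRates(namount, world@referenceRateMap, hareaCounty)
  rates <- if (calibrate)
    calibrateToFubc(ratesPre, hareaCounty, world@fubcTables,
                    world@vocabulary, world@hierarchy)
  else ratesPre
  cube <- rasterizeRates(rates, world@hierarchy, world@grid)
  list(namount = namount, ratesPreFubc = ratesPre, rates = rates,
       cube = cube)
}
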