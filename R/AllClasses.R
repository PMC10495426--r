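#' @import methods
NULL

# ---------------------------------------------------------------- grid ------

#' Regular longitude/latitude grid definition
#'
#' A regular WGS84 grid indexed row-major from the north-west corner. Cells
#' are addressed by a single integer index `g = (row - 1) * nCols + col`.
#'
#' @slot nRows,nCols integer cell counts.
#' @slot resolution numeric, degrees per cell (5/60 for the production grid).
#' @slot origin numeric(2), lon/lat of the grid's north-west corner.
#' @slot crs character, fixed to "WGS84".
#' @exportClass GridDefinition
setClass("GridDefinition",
  slots = c(nRows = "integer", nCols = "integer", resolution = "numeric",
            origin = "numeric", crs = "character"),
  validity = function(object) {
    msg <- character()
    if (object@resolution <= 0) msg <- c(msg, "resolution must be > 0")
    if (object@nRows < 1L || object@nCols < 1L)
      msg <- c(msg, "grid must have at least one row and one column")
    if (length(object@origin) != 2L)
      msg <- c(msg, "origin must be lon/lat of the NW corner")
    else {
      south <- object@origin[2] - object@nRows * object@resolution
      if (object@origin[2] > 90 + 1e-9 || south < -90 - 1e-9)
        msg <- c(msg, "grid must lie within [-90, 90] latitude")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a grid definition
#'
#' @param nRows,nCols cell counts.
#' @param resolution degrees per cell.
#' @param origin lon/lat of the north-west corner.
#' @return A [GridDefinition-class] object.
#' @examples
#' g <- gridDefinition(24, 48, 7.5)
#' nCells(g)
#' @export
gridDefinition <- function(nRows, nCols, resolution, origin = c(-180, 90)) {
  new("GridDefinition", nRows = as.integer(nRows), nCols = as.integer(nCols),
      resolution = as.numeric(resolution), origin = as.numeric(origin),
      crs = "WGS84")
}

#' Number of cells in a grid
#' @param grid a [GridDefinition-class].
#' @return integer cell count.
#' @export
nCells <- function(grid) grid@nRows * grid@nCols

#' Cell identifiers ("g0001", ...) in row-major order from the NW corner
#' @param grid a [GridDefinition-class].
#' @return character vector of cell ids.
#' @export
cellIds <- function(grid)
  sprintf("g%04d", seq_len(nCells(grid)))

#' Spherical cell areas in hectares
#'
#' Areas use the spherical approximation
#' `A = R^2 * dlon * (sin(lat_top) - sin(lat_bottom))` with R = 6371 km, so
#' they are positive and depend on latitude only.
#'
#' @param grid a [GridDefinition-class].
#' @return numeric vector, hectares per cell, row-major from the NW corner.
#' @export
cellAreaHa <- function(grid) {
  R <- 6371
  res <- grid@resolution
  latTop <- grid@origin[2] - (seq_len(grid@nRows) - 1) * res
  latBot <- latTop - res
  rowKm2 <- R^2 * (res * pi / 180) *
    (sin(latTop * pi / 180) - sin(latBot * pi / 180))
  rep(rowKm2 * 100, each = grid@nCols)
}

setMethod("show", "GridDefinition", function(object) {
  cat(sprintf("GridDefinition: %d x %d cells at %.4g deg (%s), NW corner (%g, %g)\n",
              object@nRows, object@nCols, object@resolution, object@crs,
              object@origin[1], object@origin[2]))
})

# ----------------------------------------------------- admin hierarchy ------

#' Administrative hierarchy: grid cell -> county -> country -> region
#'
#' @slot countries character vector of country ids (post-disintegration set).
#' @slot counties character vector of county ids.
#' @slot countyCountry named character, county -> country.
#' @slot membership character vector of length `nCells(grid)`: county id of
#'   each land cell, `NA` for cells outside any county.
#' @slot regions named character, country -> reporting region (IFA unit).
#' @slot events list of disintegration events, each a list with elements
#'   `parent`, `year`, `successors`.
#' @exportClass AdminHierarchy
setClass("AdminHierarchy",
  slots = c(countries = "character", counties = "character",
            countyCountry = "character", membership = "character",
            regions = "character", events = "list"),
  validity = function(object) {
    msg <- character()
    if (!setequal(names(object@countyCountry), object@counties))
      msg <- c(msg, "countyCountry must map exactly the counties")
    if (!all(object@countyCountry %in% object@countries))
      msg <- c(msg, "every county must belong to a listed country")
    land <- !is.na(object@membership)
    if (!all(object@membership[land] %in% object@counties))
      msg <- c(msg, "membership must reference listed counties")
    if (!all(object@countries %in% names(object@regions)))
      msg <- c(msg, "every country needs a region")
    for (ev in object@events) {
      if (!all(c("parent", "year", "successors") %in% names(ev)))
        msg <- c(msg, "each event needs parent, year, successors")
      else if (!all(ev$successors %in% object@countries))
        msg <- c(msg, "event successors must be listed countries")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an administrative hierarchy
#' @param countries,counties character id vectors.
#' @param countyCountry named character, county -> country.
#' @param membership character vector, county id per grid cell (NA = no county).
#' @param regions named character, country -> region.
#' @param events list of disintegration events.
#' @return An [AdminHierarchy-class] object.
#' @export
adminHierarchy <- function(countries, counties, countyCountry, membership,
                           regions, events = list()) {
  new("AdminHierarchy", countries = countries, counties = counties,
      countyCountry = countyCountry[counties], membership = membership,
      regions = regions, events = events)
}

#' Cells belonging to each county
#' @param hierarchy an [AdminHierarchy-class].
#' @return named list of integer cell indices per county.
#' @export
countyCells <- function(hierarchy) {
  idx <- which(!is.na(hierarchy@membership))
  split(idx, factor(hierarchy@membership[idx], levels = hierarchy@counties))
}

#' Country of each grid cell
#' @param hierarchy an [AdminHierarchy-class].
#' @return character vector, country id per cell (NA outside counties).
#' @export
cellCountry <- function(hierarchy) {
  out <- rep(NA_character_, length(hierarchy@membership))
  land <- !is.na(hierarchy@membership)
  out[land] <- hierarchy@countyCountry[hierarchy@membership[land]]
  out
}

#' Counties of a country
#' @param hierarchy an [AdminHierarchy-class].
#' @param country a country id.
#' @return character vector of county ids.
#' @export
countiesOf <- function(hierarchy, country)
  names(hierarchy@countyCountry)[hierarchy@countyCountry == country]

setMethod("show", "AdminHierarchy", function(object) {
  cat(sprintf("AdminHierarchy: %d countries, %d counties, %d land cells, %d event(s)\n",
              length(object@countries), length(object@counties),
              sum(!is.na(object@membership)), length(object@events)))
})

# ----------------------------------------------------------- data cubes -----

#' Crop x year x grid harvested-area cube (ha per cell)
#'
#' @slot values numeric array `crop x year x cell`, hectares per cell.
#' @slot grid the [GridDefinition-class] the cells refer to.
#' @slot years integer vector of years (second margin of `values`).
#' @exportClass HareaCube
setClass("HareaCube",
  slots = c(values = "array", grid = "GridDefinition", years = "integer"),
  validity = function(object) {
    d <- dim(object@values)
    msg <- character()
    if (length(d) != 3L) msg <- c(msg, "values must be crop x year x cell")
    else {
      if (d[2] != length(object@years)) msg <- c(msg, "year margin mismatch")
      if (d[3] != nCells(object@grid)) msg <- c(msg, "cell margin mismatch")
    }
    if (any(object@values < 0, na.rm = TRUE))
      msg <- c(msg, "harvested areas must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' N application rate cube, split by input class (kg N per ha harvested)
#'
#' @slot byClass numeric array `crop x class x year x cell` with classes
#'   SN (synthetic), MA (manure), CR (crop residues).
#' @slot grid the [GridDefinition-class].
#' @slot years integer vector of years.
#' @exportClass NRateCube
setClass("NRateCube",
  slots = c(byClass = "array", grid = "GridDefinition", years = "integer"),
  validity = function(object) {
    d <- dim(object@byClass)
    msg <- character()
    if (length(d) != 4L || d[2] != 3L)
      msg <- c(msg, "byClass must be crop x class(3) x year x cell")
    else {
      if (d[3] != length(object@years)) msg <- c(msg, "year margin mismatch")
      if (d[4] != nCells(object@grid)) msg <- c(msg, "cell margin mismatch")
    }
    if (any(object@byClass < 0, na.rm = TRUE))
      msg <- c(msg, "rates must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Total N rate (sum over SN/MA/CR) of an [NRateCube-class]
#' @param cube an [NRateCube-class].
#' @return numeric array `crop x year x cell`.
#' @export
totalRate <- function(cube) {
  stopifnot(is(cube, "NRateCube"))
  out <- cube@byClass[, 1L, , , drop = FALSE] +
    cube@byClass[, 2L, , , drop = FALSE] +
    cube@byClass[, 3L, , , drop = FALSE]
  dn <- dimnames(cube@byClass)
  array(out, dim = dim(cube@byClass)[-2L], dimnames = dn[-2L])
}

#' Fertilizer-type share cube (13 types x year x grid)
#'
#' Shares of each fertilizer type in the total N amount; they sum to 1
#' wherever the total amount is positive and to 0 elsewhere.
#'
#' @slot values numeric array `type(13) x year x cell`, fractions.
#' @slot county numeric array `type(13) x county x year` (the county-level
#'   shares the grid was rasterized from; kept for conservation audits).
#' @slot grid the [GridDefinition-class].
#' @slot years integer vector of years.
#' @exportClass TypeShareCube
setClass("TypeShareCube",
  slots = c(values = "array", county = "array", grid = "GridDefinition",
            years = "integer"),
  validity = function(object) {
    d <- dim(object@values)
    msg <- character()
    if (length(d) != 3L || d[1] != 13L)
      msg <- c(msg, "values must be type(13) x year x cell")
    if (any(object@values < -1e-12 | object@values > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "shares must lie in [0, 1]")
    s <- colSums(object@values)
    if (any(s > 1e-9 & abs(s - 1) > 1e-9))
      msg <- c(msg, "type shares must sum to 1 (or 0) per year-cell")
    if (length(msg)) msg else TRUE
  })

#' No-till surface: cell fractions and crop-wise fractions
#'
#' @slot notillArea numeric matrix `year x cell`, allocated no-till area (ha).
#' @slot cellFraction numeric matrix `year x cell`, no-till share of cropland.
#' @slot cropFraction numeric array `crop x year x cell`, no-till share of
#'   each crop's harvested area.
#' @exportClass NoTillSurface
setClass("NoTillSurface",
  slots = c(notillArea = "matrix", cellFraction = "matrix",
            cropFraction = "array"),
  validity = function(object) {
    msg <- character()
    if (any(object@cellFraction < -1e-12 | object@cellFraction > 1 + 1e-12))
      msg <- c(msg, "cell fractions must lie in [0, 1]")
    if (any(object@cropFraction < -1e-12 | object@cropFraction > 1 + 1e-12))
      msg <- c(msg, "crop fractions must lie in [0, 1]")
    if (any(object@notillArea < 0)) msg <- c(msg, "areas must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Placement cube: surface/deep fractions per crop, fertilizer, year, cell
#'
#' Deep-placement fractions are a deterministic function of the crop no-till
#' fraction and the fertilizer category: injected synthetic types are always
#' deep; manure and crop residues are incorporated only where tillage happens
#' (deep = 1 - NoTill); other synthetic types follow the base-topdressing
#' split (deep = baseRatio * NoTill). Only the no-till array is stored; the
#' crop x fertilizer x placement x year x cell view is computed on demand by
#' [placementDeep()] / [placementSurface()], and surface + deep = 1 exactly.
#'
#' @slot noTill numeric array `crop x year x cell` of no-till fractions.
#' @slot injected character, the always-deep (injected) fertilizer types.
#' @slot baseRatio numeric scalar, base-topdressing application ratio (0.7).
#' @slot vocabulary the vocabulary list (for the fertilizer-type order).
#' @exportClass PlacementCube
setClass("PlacementCube",
  slots = c(noTill = "array", injected = "character", baseRatio = "numeric",
            vocabulary = "list"),
  validity = function(object) {
    msg <- character()
    if (any(object@noTill < -1e-12 | object@noTill > 1 + 1e-12))
      msg <- c(msg, "no-till fractions must lie in [0, 1]")
    if (object@baseRatio < 0 || object@baseRatio > 1)
      msg <- c(msg, "baseRatio must lie in [0, 1]")
    bad <- setdiff(object@injected, object@vocabulary$snTypes)
    if (length(bad))
      msg <- c(msg, paste("injected types must be synthetic:",
                          paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Self-consistent synthetic world with known ground truth
#'
#' Bundle of every input panel and raster the reconstruction consumes, built
#' from a single known ground truth (see [generateWorld()]). Panels are
#' mutually consistent by construction when noise is disabled.
#'
#' @slot vocabulary the label vocabulary, see [nfertVocabulary()].
#' @slot grid,hierarchy spatial scaffold.
#' @slot config the generating configuration (see [worldConfig()]).
#' @slot referenceHareaMap crop x county harvested area (ha) for year 2000.
#' @slot countryHareaSeries crop x country x year national harvested area,
#'   with disintegration gaps (parent before the split, successors after).
#' @slot croplandCube list(rice, upland): year x cell cropland areas (ha).
#' @slot priorNamountPanel class x county x year amounts (kg N), 1961-2014.
#' @slot faoNamountSeries class x country x year amounts (kg N), full period.
#' @slot referenceRateMap crop x class x county rates (kg N/ha), year 2000.
#' @slot fubcTables list(anchors = cro2 x country x anchor-year amounts,
#'   historic = cro2 x country x year amounts for 1978-2001).
#' @slot typeConsumptionPanel list(values = snType x region x year kg N with
#'   injected missingness, totalSn = region x year, missingMask).
#' @slot covariatePanel list(gdp, population, croplandArea: country x year;
#'   ruralPopulation; croplandUseFraction per country).
#' @slot notillDrivers list(fieldSize, erosion, aridity, rainfedFraction cell
#'   rasters; incomeClass per country; censusCountries; censusNotill).
#' @slot groundTruth list with the true county harvested areas, class
#'   amounts, crop rates, type shares and national no-till areas.
#' @exportClass SyntheticWorld
setClass("SyntheticWorld",
  slots = c(vocabulary = "list", grid = "GridDefinition",
            hierarchy = "AdminHierarchy", config = "list",
            referenceHareaMap = "matrix", countryHareaSeries = "array",
            croplandCube = "list", priorNamountPanel = "array",
            faoNamountSeries = "array", referenceRateMap = "array",
            fubcTables = "list", typeConsumptionPanel = "list",
            covariatePanel = "list", notillDrivers = "list",
            groundTruth = "list"),
  validity = function(object) {
    msg <- character()
    nonneg <- function(x, what)
      if (any(x < 0, na.rm = TRUE)) paste(what, "must be >= 0") else NULL
    msg <- c(msg,
             nonneg(object@referenceHareaMap, "reference harvested areas"),
             nonneg(object@countryHareaSeries, "national harvested areas"),
             nonneg(object@croplandCube$rice, "cropland areas"),
             nonneg(object@croplandCube$upland, "cropland areas"),
             nonneg(object@priorNamountPanel, "prior N amounts"),
             nonneg(object@faoNamountSeries, "national N amounts"),
             nonneg(object@referenceRateMap, "reference rates"),
             nonneg(object@typeConsumptionPanel$values, "type consumption"))
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SyntheticWorld", function(object) {
  yrs <- object@config$years
  cat(sprintf("SyntheticWorld: %d countries / %d counties on a %dx%d grid, %d-%d (seed %d)\n",
              length(object@hierarchy@countries),
              length(object@hierarchy@counties),
              object@grid@nRows, object@grid@nCols,
              min(yrs), max(yrs), object@config$seed))
})

setMethod("show", "HareaCube", function(object) {
  cat(sprintf("HareaCube: %d crops x %d years x %d cells, total %.4g ha\n",
              dim(object@values)[1], dim(object@values)[2],
              dim(object@values)[3], sum(object@values)))
})

setMethod("show", "NRateCube", function(object) {
  cat(sprintf("NRateCube: %d crops x SN/MA/CR x %d years x %d cells\n",
              dim(object@byClass)[1], dim(object@byClass)[3],
              dim(object@byClass)[4]))
})

setMethod("show", "TypeShareCube", function(object) {
  cat(sprintf("TypeShareCube: 13 types x %d years x %d cells\n",
              dim(object@values)[2], dim(object@values)[3]))
})

setMethod("show", "PlacementCube", function(object) {
  cat(sprintf("PlacementCube: injected = {%s}, base-topdressing ratio %.2f\n",
              paste(object@injected, collapse = ", "), object@baseRatio))
})

setMethod("show", "NoTillSurface", function(object) {
  cat(sprintf("NoTillSurface: %d years x %d cells, %.4g ha no-till in final year\n",
              nrow(object@notillArea), ncol(object@notillArea),
              sum(object@notillArea[nrow(object@notillArea), ])))
})

# ------------------------------------------------------------ accessors -----

#' Extract the value array of a cube
#' @param x a cube object.
#' @return the underlying numeric array (with dimnames).
#' @export
cubeValues <- function(x) {
  if (is(x, "HareaCube")) return(x@values)
  if (is(x, "NRateCube")) return(x@byClass)
  if (is(x, "TypeShareCube")) return(x@values)
  stop("no value array for class ", class(x))
}

#' Years covered by a cube
#' @param x a cube object with a `years` slot.
#' @return integer vector of years.
#' @export
cubeYears <- function(x) x@years
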