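# Harvested-area reconstruction: a year-2000 county reference map is extended
# through time by national ratios, split to the grid in proportion to
# cropland, and finally matched back to the national totals.

#' Fill disintegration gaps in a national harvested-area series
#'
#' Countries that split leave a gap: the parent reports before the split year
#' and the successors after it. Parent-era values are distributed to the
#' successors using each successor's share of the total harvested area in the
#' first year after disintegration (per crop). Years at or after the split
#' are untouched. If all successors report zero in that first year the parent
#' value is split equally and a warning is issued.
#'
#' @param national numeric array `crop x country x year`; must contain the
#'   parent column of each event.
#' @param events list of events, each with `parent`, `year`, `successors`.
#' @return The national array restricted to non-parent countries, with
#'   parent-era successor values filled in.
#' @export
handleDisintegration <- function(national, events) {
  yrs <- as.integer(dimnames(national)[[3]])
  for (ev in events) {
    if (!ev$parent %in% dimnames(national)[[2]]) next
    pre <- yrs < ev$year
    first <- as.character(ev$year)
    for (cro in dimnames(national)[[1]]) {
      shares <- national[cro, ev$successors, first]
      if (!any(is.finite(shares)) || sum(shares, na.rm = TRUE) == 0) {
        warning("all successors of ", ev$parent, " report zero ", cro,
                " area in ", first, "; splitting equally", call. = FALSE)
        shares <- rep(1, length(ev$successors))
      }
      shares <- shares / sum(shares, na.rm = TRUE)
      shares[!is.finite(shares)] <- 0
      national[cro, ev$successors, pre] <-
        outer(shares, national[cro, ev$parent, pre])
    }
    keep <- setdiff(dimnames(national)[[2]], ev$parent)
    national <- national[, keep, , drop = FALSE]
  }
  national
}

#' Extend a year-2000 county reference map through time by national ratios
#'
#' Each county inherits its country's annual change:
#' `Harea[cro, y, i] = ref[cro, i] * national[cro, j, y] / national[cro, j, 2000]`.
#' If the reference-year national value is zero while later years are
#' positive, the spatial share is undefined and the national value is spread
#' uniformly over the country's counties (flagged with a warning).
#'
#' @param refMap numeric matrix `crop x county`, harvested area (ha) in the
#'   reference year.
#' @param national numeric array `crop x country x year` (gap-free, see
#'   [handleDisintegration()]).
#' @param hierarchy an [AdminHierarchy-class].
#' @param referenceYear the reference year of `refMap` (2000).
#' @return numeric array `crop x county x year`.
#' @export
extendHarvestedArea <- function(refMap, national, hierarchy,
                                referenceYear = 2000L) {
  crops <- rownames(refMap)
  counties <- colnames(refMap)
  yrs <- dimnames(national)[[3]]
  out <- array(0, c(length(crops), length(counties), length(yrs)),
               dimnames = list(crops, counties, yrs))
  for (j in hierarchy@countries) {
    cnt <- intersect(countiesOf(hierarchy, j), counties)
    if (!length(cnt)) next
    nat <- national[crops, j, , drop = TRUE]
    if (is.null(dim(nat))) nat <- matrix(nat, nrow = 1,
                                         dimnames = list(crops, yrs))
    nat[is.na(nat)] <- 0
    ref <- nat[, as.character(referenceYear)]
    ratio <- nat / ifelse(ref > 0, ref, 1)
    for (i in cnt) out[, i, ] <- refMap[, i] * ratio
    undef <- ref == 0 & rowSums(nat) > 0
    if (any(undef)) {
      warning("zero reference-year national area for ",
              paste(crops[undef], collapse = ", "), " in ", j,
              "; spreading uniformly over counties", call. = FALSE)
      for (cro in crops[undef])
        out[cro, cnt, ] <- matrix(rep(nat[cro, ] / length(cnt),
                                      each = length(cnt)),
                                  nrow = length(cnt))
    }
  }
  out
}

#' Disaggregate county harvested areas to the grid
#'
#' County totals are spread over the county's cells in proportion to cropland
#' area: the rice layer for rice, the upland layer for every other crop. A
#' county with crop area but zero matching cropland in a year is spread
#' uniformly over its cells (flagged with a warning).
#'
#' @param countyTable numeric array `crop x county x year` (ha).
#' @param cropland list with `rice` and `upland` matrices `year x cell` (ha).
#' @param hierarchy an [AdminHierarchy-class].
#' @param grid the [GridDefinition-class].
#' @return An [HareaCube-class].
#' @export
disaggregateToGrid <- function(countyTable, cropland, hierarchy, grid) {
  crops <- dimnames(countyTable)[[1]]
  yrs <- dimnames(countyTable)[[3]]
  counties <- dimnames(countyTable)[[2]]
  cellsOf <- countyCells(hierarchy)
  vals <- array(0, c(length(crops), length(yrs), nCells(grid)),
                dimnames = list(crops, yrs, cellIds(grid)))
  riceRow <- crops == "Rice"
  fallback <- FALSE
  for (i in counties) {
    cells <- cellsOf[[i]]
    if (!length(cells)) next
    for (k in seq_along(yrs)) {
      for (layer in c("rice", "upland")) {
        cl <- cropland[[layer]][yrs[k], cells]
        tot <- sum(cl)
        sel <- if (layer == "rice") riceRow else !riceRow
        cv <- countyTable[sel, i, k]
        if (!any(cv > 0)) next
        share <- if (tot > 0) cl / tot else {
          fallback <- TRUE
          rep(1 / length(cells), length(cells))
        }
        vals[sel, k, cells] <- outer(cv, share)
      }
    }
  }
  if (fallback)
    warning("county crop area with zero matching cropland; ",
            "spread uniformly over county cells", call. = FALSE)
  new("HareaCube", values = vals, grid = grid,
      years = as.integer(yrs))
}

#' Match a gridded harvested-area cube to national totals
#'
#' Rescales each (crop, country, year) so the cube's national sum equals the
#' statistical value exactly. A zero target zeroes the cells; a zero cube sum
#' with a positive target is spread uniformly over the country's cells with
#' cropland (or over all its cells when no cropland layer is given).
#'
#' @param cube an [HareaCube-class].
#' @param national numeric array `crop x country x year` (gap-free).
#' @param hierarchy an [AdminHierarchy-class].
#' @param cropland optional cropland list (`rice`, `upland`) used to pick the
#'   cells for uniform spreading.
#' @return The matched [HareaCube-class].
#' @export
matchNationalTotals <- function(cube, national, hierarchy, cropland = NULL) {
  vals <- cube@values
  crops <- dimnames(vals)[[1]]
  yrs <- dimnames(vals)[[2]]
  ctry <- cellCountry(hierarchy)
  for (j in intersect(hierarchy@countries, dimnames(national)[[2]])) {
    cells <- which(ctry == j)
    if (!length(cells)) next
    block <- vals[, , cells, drop = FALSE]
    sums <- rowSums(block, dims = 2L)                 # crop x year
    target <- national[crops, j, yrs, drop = TRUE]
    if (is.null(dim(target)))
      target <- matrix(target, nrow = length(crops),
                       dimnames = list(crops, yrs))
    target[is.na(target)] <- 0
    fac <- ifelse(target == 0, 0, ifelse(sums > 0, target / sums, NA_real_))
    vals[, , cells] <- block * as.vector(fac)         # recycles over cells
    need <- which(is.na(fac), arr.ind = TRUE)
    if (nrow(need)) {
      spreadCells <- cells
      if (!is.null(cropland)) {
        cl <- cropland$rice + cropland$upland
        withCl <- cells[colSums(cl[yrs, cells, drop = FALSE]) > 0]
        if (length(withCl)) spreadCells <- withCl
      }
      for (r in seq_len(nrow(need))) {
        cro <- need[r, 1]; k <- need[r, 2]
        vals[cro, k, cells] <- 0
        vals[cro, k, spreadCells] <- target[cro, k] / length(spreadCells)
      }
    }
  }
  new("HareaCube", values = vals, grid = cube@grid, years = cube@years)
}

#' Run the full harvested-area stage on a synthetic world
#'
#' Disintegration handling, reference-map extension, gridding, and national
#' matching, in that order.
#'
#' @param world a [SyntheticWorld-class].
#' @return list with the gap-free `national` series, the `county` table and
#'   the matched [HareaCube-class] `cube`.
#' @export
buildHarvestedArea <- function(world) {
  national <- handleDisintegration(world@countryHareaSeries,
                                   world@hierarchy@events)
  county <- extendHarvestedArea(world@referenceHareaMap, national,
                                world@hierarchy)
  cube <- disaggregateToGrid(county, world@croplandCube, world@hierarchy,
                             world@grid)
  cube <- matchNationalTotals(cube, national, world@hierarchy,
                              world@croplandCube)
  # the matched cube is the authoritative gridded product; keep the county
  # table consistent with it for the county-level rate computations
  countyMatched <- county
  cellsOf <- countyCells(world@hierarchy)
  for (i in dimnames(county)[[2]])
    countyMatched[, i, ] <- rowSums(cube@values[, , cellsOf[[i]],
                                                drop = FALSE], dims = 2L)
  list(national = national, county = countyMatched, cube = cube)
}
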