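# Placement: surface vs deep fractions per crop, fertilizer and cell, driven
# by a gridded no-till surface. The surface is built in four steps: national
# no-till areas (census or regression on cropland per rural capita),
# eligibility screening (rain-fed suitable crops, field size, income), a
# four-predictor logit probability, and ranked greedy allocation.

#' Predict national no-till areas
#'
#' Country-years with census data use the census directly (summed over
#' provinces). All other country-years are predicted from cropland area per
#' rural capita with a monotone non-decreasing logistic regression fitted to
#' the census observations (quasibinomial GLM on log cropland-per-capita; a
#' negative fitted slope is replaced by an intercept-only fit so the monotone
#' contract always holds). Fractions are clipped to [0, 1] and multiplied by
#' cropland area. A zero rural population gets the model's upper asymptote.
#'
#' @param ruralPopulation,croplandArea numeric matrices `country x year`.
#' @param censusNotill named list (by country) of `province x year` no-till
#'   area matrices.
#' @param hierarchy an [AdminHierarchy-class].
#' @return numeric matrix `country x year` of no-till areas (ha).
#' @export
predictNationalNotill <- function(ruralPopulation, croplandArea, censusNotill,
                                  hierarchy) {
  countries <- hierarchy@countries
  yc <- colnames(croplandArea)
  cpc <- croplandArea[countries, , drop = FALSE] /
    ruralPopulation[countries, , drop = FALSE]
  lcpc <- log(cpc)
  train <- NULL
  for (j in intersect(names(censusNotill), rownames(croplandArea))) {
    cyrs <- intersect(colnames(censusNotill[[j]]), colnames(croplandArea))
    if (!length(cyrs)) next
    frac <- pmin(1, pmax(0, colSums(censusNotill[[j]][, cyrs, drop = FALSE]) /
                           croplandArea[j, cyrs]))
    train <- rbind(train, data.frame(frac = frac, lcpc = lcpc[j, cyrs]))
  }
  if (is.null(train) || nrow(train) < 2L)
    stop("need census no-till observations to fit the national model",
         call. = FALSE)
  train <- train[is.finite(train$lcpc), ]
  fit <- suppressWarnings(stats::glm(frac ~ lcpc, family = stats::quasibinomial(),
                                     data = train))
  if (stats::coef(fit)["lcpc"] < 0) {
    warning("census no-till fraction decreases with cropland per capita; ",
            "falling back to an intercept-only model", call. = FALSE)
    fit <- suppressWarnings(stats::glm(frac ~ 1, family = stats::quasibinomial(),
                                       data = train))
  }
  frac <- matrix(NA_real_, length(countries), length(yc),
                 dimnames = list(countries, yc))
  finite <- is.finite(lcpc)
  frac[finite] <- stats::predict(fit,
                                 newdata = data.frame(lcpc = lcpc[finite]),
                                 type = "response")
  if (any(!finite)) {
    warning("zero rural population encountered; using the model's upper ",
            "asymptote", call. = FALSE)
    frac[!finite] <- 1
  }
  frac <- pmin(1, pmax(0, frac))
  area <- frac * croplandArea[countries, , drop = FALSE]
  for (j in intersect(names(censusNotill), countries)) {
    cyrs <- intersect(colnames(censusNotill[[j]]), yc)
    area[j, cyrs] <- colSums(censusNotill[[j]][, cyrs, drop = FALSE])
  }
  area
}

#' Potential no-till area per cell and year
#'
#' The rain-fed harvested area of the 11 no-till-suitable annual crops,
#' zeroed in low-income countries' cells without dominant large fields
#' (high-income countries keep all field sizes).
#'
#' @param harea an [HareaCube-class].
#' @param drivers list with `rainfedFraction` and `fieldSize` cell rasters and
#'   `incomeClass` (named per-country, "high"/"low").
#' @param vocabulary the vocabulary list (suitable-crop set).
#' @param hierarchy an [AdminHierarchy-class].
#' @param largeFieldClass smallest field-size class counted as "dominant
#'   large" (default 3).
#' @return numeric matrix `year x cell` of potential no-till area (ha).
#' @export
allocatePotentialNotill <- function(harea, drivers, vocabulary, hierarchy,
                                    largeFieldClass = 3) {
  suitable <- vocabulary$notillCrops
  vals <- harea@values[suitable, , , drop = FALSE]
  potential <- colSums(vals)                          # year x cell
  potential <- sweep(potential, 2, drivers$rainfedFraction, "*")
  ctry <- cellCountry(hierarchy)
  lowIncome <- !is.na(ctry) & drivers$incomeClass[ctry] == "low"
  ineligible <- lowIncome & drivers$fieldSize < largeFieldClass
  potential[, ineligible] <- 0
  potential[, is.na(ctry)] <- 0
  potential
}

#' Default logit parameters: unit slopes at per-driver medians
#'
#' Placeholder coefficients for the no-till occurrence logit when no fitted
#' values are supplied: slope 1 for every predictor and midpoint at the
#' median of the driver over land cells.
#'
#' @param drivers driver list (needs `erosion`, `aridity`, `fieldSize`).
#' @param cropMix numeric `year x cell` matrix (or cell vector) of the
#'   suitable-crop area share.
#' @return list of `list(k, xmid)` per predictor.
#' @export
defaultLogitParams <- function(drivers, cropMix) {
  med <- function(x) stats::median(x[is.finite(x)])
  list(erosion = list(k = 1, xmid = med(drivers$erosion)),
       aridity = list(k = 1, xmid = med(drivers$aridity)),
       cropMix = list(k = 1, xmid = med(cropMix)),
       fieldSize = list(k = 1, xmid = med(drivers$fieldSize)))
}

#' No-till occurrence probability per cell
#'
#' Four-predictor logistic surface
#' `NTA = 1 / (1 + exp(-sum_n k_n (vx_n - xmid_n)))` over water erosion,
#' aridity, crop mix and field size. Cells with a missing driver value get
#' probability 0 (flagged).
#'
#' @param drivers driver list with `erosion`, `aridity`, `fieldSize` cell
#'   rasters.
#' @param params list of `list(k, xmid)` for `erosion`, `aridity`, `cropMix`,
#'   `fieldSize` (see [defaultLogitParams()]).
#' @param cropMix numeric `year x cell` matrix of suitable-crop area shares.
#' @return numeric `year x cell` matrix of probabilities in (0, 1).
#' @export
notillProbability <- function(drivers, params, cropMix) {
  need <- c("erosion", "aridity", "cropMix", "fieldSize")
  if (!all(need %in% names(params)))
    stop("logit parameters must cover: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(dim(cropMix))) cropMix <- matrix(cropMix, nrow = 1)
  eta <- params$erosion$k * (drivers$erosion - params$erosion$xmid) +
    params$aridity$k * (drivers$aridity - params$aridity$xmid) +
    params$fieldSize$k * (drivers$fieldSize - params$fieldSize$xmid)
  etaM <- sweep(params$cropMix$k * (cropMix - params$cropMix$xmid), 2, eta,
                "+")
  p <- stats::plogis(etaM)
  bad <- !is.finite(p)
  if (any(bad)) {
    warning("missing driver values; probability set to 0", call. = FALSE)
    p[bad] <- 0
  }
  p
}

#' Downscale national no-till areas to cells by ranked probability
#'
#' Within each country and year, cells are sorted by decreasing no-till
#' probability (ties broken by cell index) and selected greedily; each
#' selected cell contributes `potential * probability`, and the last cell is
#' selected partially so the allocated sum hits the national target exactly.
#' A target above the total achievable contribution selects everything and
#' logs the shortfall.
#'
#' @param targets numeric matrix `country x year` of no-till areas (ha).
#' @param potential numeric matrix `year x cell` (see
#'   [allocatePotentialNotill()]).
#' @param probability numeric matrix `year x cell` (see
#'   [notillProbability()]).
#' @param hierarchy an [AdminHierarchy-class].
#' @return numeric matrix `year x cell` of allocated no-till area (ha).
#' @export
downscaleNotill <- function(targets, potential, probability, hierarchy) {
  yc <- rownames(potential)
  out <- matrix(0, nrow(potential), ncol(potential),
                dimnames = dimnames(potential))
  ctry <- cellCountry(hierarchy)
  shortfall <- 0
  for (j in intersect(hierarchy@countries, rownames(targets))) {
    cells <- which(!is.na(ctry) & ctry == j)
    if (!length(cells)) next
    for (k in seq_along(yc)) {
      target <- targets[j, yc[k]]
      if (!is.finite(target) || target <= 0) next
      pot <- potential[k, cells]
      prob <- probability[k, cells]
      contrib <- pot * prob
      ord <- order(-prob, cells)                      # ties: by cell index
      cum <- cumsum(contrib[ord])
      achievable <- if (length(cum)) cum[length(cum)] else 0
      if (target >= achievable) {
        shortfall <- shortfall + (target - achievable)
        out[k, cells] <- contrib
        next
      }
      cut <- which(cum >= target)[1]
      take <- contrib[ord][seq_len(cut)]
      take[cut] <- target - if (cut > 1) cum[cut - 1] else 0
      out[k, cells[ord[seq_len(cut)]]] <- take
    }
  }
  if (shortfall > 0)
    warning(sprintf("no-till targets exceed achievable potential by %.4g ha",
                    shortfall), call. = FALSE)
  out
}

#' Crop-wise no-till fractions from the allocated cell areas
#'
#' The no-till area of a cell is split across crops in proportion to
#' harvested area; each crop's fraction is its no-till area over its
#' harvested area, clipped to [0, 1] (crops and cells with zero harvested
#' area get 0).
#'
#' @param notillArea numeric matrix `year x cell` (ha).
#' @param harea an [HareaCube-class].
#' @param cropland optional cropland list to derive the cell fraction of
#'   cropland under no-till.
#' @return A [NoTillSurface-class].
#' @export
cropNotillFraction <- function(notillArea, harea, cropland = NULL) {
  totH <- colSums(harea@values)                       # year x cell
  cellFrac <- notillArea / ifelse(totH > 0, totH, 1)
  if (!is.null(cropland)) {
    totC <- cropland$rice + cropland$upland
    cellFrac <- notillArea / ifelse(totC > 0, totC, 1)
    cellFrac[totC <= 0] <- 0
  } else cellFrac[totH <= 0] <- 0
  cellFrac[] <- pmin(1, pmax(0, cellFrac))
  d <- dim(harea@values)
  frac <- pmin(1, notillArea / ifelse(totH > 0, totH, 1))
  frac[totH <= 0] <- 0
  cropFraction <- array(0, d, dimnames = dimnames(harea@values))
  hasArea <- harea@values > 0
  cropFraction[hasArea] <- rep(frac, each = d[1])[hasArea]
  new("NoTillSurface", notillArea = notillArea, cellFraction = cellFrac,
      cropFraction = cropFraction)
}

#' Surface/deep placement fractions
#'
#' Deep placement is 1 for injected fertilizers (anhydrous ammonia and N
#' solutions by default — both are soil-injected; set
#' `literalInjected = TRUE` to use the {AA, AN} set instead),
#' `baseRatio * NoTill` for the other synthetic types (the base fraction of a
#' split application is incorporated only under no-till seeding), and
#' `1 - NoTill` for manure and crop residues (incorporated by tillage).
#' Surface is the complement, so surface + deep = 1 exactly.
#'
#' @param notill a [NoTillSurface-class].
#' @param vocabulary the vocabulary list.
#' @param injected character, the always-deep types (default `c("AA", "NS")`).
#' @param baseRatio base-topdressing application ratio (default 0.7).
#' @param literalInjected logical; use the `c("AA", "AN")` set.
#' @return A [PlacementCube-class].
#' @export
placementShares <- function(notill, vocabulary, injected = c("AA", "NS"),
                            baseRatio = 0.7, literalInjected = FALSE) {
  if (literalInjected) injected <- c("AA", "AN")
  new("PlacementCube", noTill = notill@cropFraction, injected = injected,
      baseRatio = baseRatio, vocabulary = vocabulary)
}

#' Deep-placement fraction for one fertilizer type
#' @param placement a [PlacementCube-class].
#' @param fertilizer one of the 13 fertilizer-type labels.
#' @return numeric array `crop x year x cell` of deep fractions.
#' @export
placementDeep <- function(placement, fertilizer) {
  stopifnot(fertilizer %in% placement@vocabulary$fertilizerTypes)
  nt <- placement@noTill
  if (fertilizer %in% placement@injected) {
    out <- array(1, dim(nt), dimnames = dimnames(nt))
  } else if (fertilizer %in% c("CR", "MA")) {
    out <- 1 - nt
  } else {
    out <- placement@baseRatio * nt
  }
  out
}

#' Surface-placement fraction for one fertilizer type
#' @inheritParams placementDeep
#' @return numeric array `crop x year x cell` of surface fractions.
#' @export
placementSurface <- function(placement, fertilizer)
  1 - placementDeep(placement, fertilizer)

#' Run the full placement stage on a synthetic world
#'
#' @param world a [SyntheticWorld-class].
#' @param harea an [HareaCube-class] from [buildHarvestedArea()].
#' @param logitParams logit coefficients (see [defaultLogitParams()]).
#' @param injected the always-deep fertilizer set.
#' @param baseRatio base-topdressing ratio.
#' @return list with `national` targets, `potential`, `probability`,
#'   `surface` ([NoTillSurface-class]) and `placement`
#'   ([PlacementCube-class]).
#' @export
buildPlacement <- function(world, harea, logitParams = NULL,
                           injected = c("AA", "NS"), baseRatio = 0.7) {
  drv <- world@notillDrivers
  national <- predictNationalNotill(world@covariatePanel$ruralPopulation,
                                    world@covariatePanel$croplandArea,
                                    drv$censusNotill, world@hierarchy)
  totHarea <- colSums(harea@values)                   # year x cell
  suitH <- colSums(harea@values[world@vocabulary$notillCrops, , ,
                                drop = FALSE])
  cropMix <- suitH / ifelse(totHarea > 0, totHarea, 1)
  cropMix[totHarea <= 0] <- 0
  if (is.null(logitParams)) logitParams <- defaultLogitParams(drv, cropMix)
  potential <- allocatePotentialNotill(harea, drv, world@vocabulary,
                                       world@hierarchy)
  probability <- notillProbability(drv, logitParams, cropMix)
  area <- downscaleNotill(national, potential, probability, world@hierarchy)
  surface <- cropNotillFraction(area, harea, world@croplandCube)
  list(national = national, potential = potential, probability = probability,
       surface = surface,
       placement = placementShares(surface, world@vocabulary,
                                   injected = injected,
                                   baseRatio = baseRatio))
}
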