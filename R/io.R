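# Published-layout output: one HDF5 file per crop with 26 records named
# "{Fertilizer type}_{Placement}" (kg N per ha of harvested area), one
# harvested-area file with 21 crop records (ha per grid cell), plus the
# pipeline driver that runs every stage in order.

#' Write the per-crop HDF5 output bundle
#'
#' Each crop's file `N_rate_{Crop name}_{y0}-{y1}.h5` holds 26 records
#' `{type}_{placement}` with value
#' `totalRate * typeShare * placementFraction` (kg N per ha of harvested
#' area), dimensioned year x row x col; the harvested-area file holds one
#' record per crop (ha per cell). Multiplying a record by the harvested area
#' and summing over the 26 records recovers the crop's total N amount.
#'
#' @param rateCube an [NRateCube-class].
#' @param shares a [TypeShareCube-class].
#' @param placement a [PlacementCube-class].
#' @param harea an [HareaCube-class].
#' @param dir output directory (created if needed).
#' @param vocabulary the vocabulary list.
#' @param enDash logical; reproduce the en-dash in the deposited file names
#'   instead of the portable plain hyphen.
#' @return Invisibly, a list with `rateFiles` (named by crop) and `areaFile`.
#' @export
writeOutputs <- function(rateCube, shares, placement, harea, dir,
                         vocabulary = nfertVocabulary(), enDash = FALSE) {
  grid <- rateCube@grid
  yrs <- rateCube@years
  stopifnot(identical(yrs, harea@years), identical(yrs, shares@years))
  if (!identical(dim(rateCube@byClass)[4], dim(shares@values)[3]) ||
      !identical(dim(rateCube@byClass)[4], dim(harea@values)[3]))
    stop("cube dimensions disagree; nothing written", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dash <- if (enDash) "–" else "-"
  span <- paste0(min(yrs), dash, max(yrs))
  total <- totalRate(rateCube)                        # crop x year x cell
  asGrid <- function(yearCell) {
    # year x cell (row-major cells) -> year x row x col
    aperm(array(yearCell, c(length(yrs), grid@nCols, grid@nRows)),
          c(1, 3, 2))
  }
  rateFiles <- character()
  for (cro in vocabulary$cropGroups) {
    fn <- file.path(dir, sprintf("N_rate_%s_%s.h5", cro, span))
    if (file.exists(fn)) unlink(fn)
    rhdf5::h5createFile(fn)
    for (f in vocabulary$fertilizerTypes) {
      deepFrac <- placementDeep(placement, f)[cro, , ]
      base <- total[cro, , ] * shares@values[f, , ]   # year x cell
      for (p in vocabulary$placements) {
        pf <- if (p == "Deep") deepFrac else 1 - deepFrac
        rec <- asGrid(base * pf)
        nm <- paste0(f, "_", p)
        rhdf5::h5createDataset(fn, nm, dims = dim(rec), level = 4,
                               storage.mode = "double")
        rhdf5::h5write(rec, fn, nm)
      }
    }
    writeGridAttributes(fn, grid, yrs,
                        units = "kg N per hectare of harvested area")
    rateFiles[cro] <- fn
  }
  areaFile <- file.path(dir, sprintf("Harvested_area_%s.h5", span))
  if (file.exists(areaFile)) unlink(areaFile)
  rhdf5::h5createFile(areaFile)
  for (cro in vocabulary$cropGroups) {
    rec <- asGrid(harea@values[cro, , ])
    rhdf5::h5createDataset(areaFile, cro, dims = dim(rec), level = 4,
                           storage.mode = "double")
    rhdf5::h5write(rec, areaFile, cro)
  }
  writeGridAttributes(areaFile, grid, yrs, units = "hectare per grid cell")
  rhdf5::h5closeAll()
  invisible(list(rateFiles = rateFiles, areaFile = areaFile))
}

writeGridAttributes <- function(fn, grid, yrs, units) {
  fid <- rhdf5::H5Fopen(fn)
  on.exit(rhdf5::H5Fclose(fid))
  rhdf5::h5writeAttribute(grid@crs, fid, "crs")
  rhdf5::h5writeAttribute(grid@resolution, fid, "resolution_deg")
  rhdf5::h5writeAttribute(grid@origin, fid, "nw_corner_lon_lat")
  rhdf5::h5writeAttribute(as.integer(yrs), fid, "years")
  rhdf5::h5writeAttribute(units, fid, "units")
}

#' Read one record from an output file
#'
#' @param file path to an output HDF5 file.
#' @param record record name (`"{type}_{placement}"` or a crop name).
#' @return numeric array `year x row x col`.
#' @export
readOutputRecord <- function(file, record) {
  on.exit(rhdf5::h5closeAll())
  rhdf5::h5read(file, record)
}

#' List the records of an output file
#' @param file path to an output HDF5 file.
#' @return character vector of record names.
#' @export
listOutputRecords <- function(file) {
  on.exit(rhdf5::h5closeAll())
  info <- rhdf5::h5ls(file)
  info$name[info$otype == "H5I_DATASET"]
}

#' Run the full reconstruction pipeline
#'
#' Executes the stages in their fixed order — harvested area (disintegration,
#' extension, gridding, matching), class amounts and crop rates (extension,
#' SN correction, constant-ratio split, FUBC calibration), type shares
#' (imputation, 13-way shares), placement (national no-till, eligibility,
#' logit, ranked allocation, surface/deep split), optional HDF5 output, and
#' the conservation audits — and collects a structured log of every warning
#' raised (correction factors and fallbacks flag themselves through
#' warnings).
#'
#' @param world a [SyntheticWorld-class].
#' @param config list of run settings: `logitParams` (mandatory unless
#'   `useDefaultLogit = TRUE`), `injected` fertilizer set, `baseRatio`,
#'   `calibrate` (FUBC calibration on/off), `imputeM`, `seed`, `outDir`
#'   (NULL = no files).
#' @return list of class `NfertRun` with elements `harea`, `napp`, `shares`,
#'   `placement`, `outputs`, `conservation`, `log`.
#' @export
runPipeline <- function(world, config = list()) {
  defaults <- list(logitParams = NULL, useDefaultLogit = FALSE,
                   injected = c("AA", "NS"), baseRatio = 0.7,
                   calibrate = TRUE, imputeM = 5L, seed = 1L, outDir = NULL)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$logitParams) && !isTRUE(config$useDefaultLogit))
    stop("no logit-parameter block: supply config$logitParams (slope and ",
         "midpoint per driver, see defaultLogitParams()) or set ",
         "useDefaultLogit = TRUE", call. = FALSE)
  logLines <- character()
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    logLines <<- c(logLines, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  harea <- collect(buildHarvestedArea(world))
  napp <- collect(buildNApplication(world, harea$county,
                                    calibrate = config$calibrate))
  imputed <- collect(imputeMissingConsumption(world@typeConsumptionPanel,
                                              world@covariatePanel,
                                              world@hierarchy,
                                              m = config$imputeM,
                                              seed = config$seed))
  # class amounts implied by the calibrated rates keep the share/rate
  # factorization exact in calibrated years
  counties <- dimnames(napp$rates)[[3]]
  yc <- dimnames(napp$rates)[[4]]
  postAmount <- array(0, c(3L, length(counties), length(yc)),
                      dimnames = list(world@vocabulary$classes, counties, yc))
  for (f in world@vocabulary$classes)
    postAmount[f, , ] <- colSums(napp$rates[, f, , ] *
                                   harea$county[, , yc, drop = FALSE])
  shares <- collect(computeTypeShares(imputed, postAmount, world@hierarchy,
                                      world@grid, world@vocabulary))
  placement <- collect(buildPlacement(world, harea$cube,
                                      logitParams = config$logitParams,
                                      injected = config$injected,
                                      baseRatio = config$baseRatio))
  run <- list(harea = harea,
              napp = c(napp, list(postAmount = postAmount)),
              imputedPanel = imputed, shares = shares,
              placement = placement, outputs = NULL, log = logLines)
  if (!is.null(config$outDir))
    run$outputs <- writeOutputs(napp$cube, shares, placement$placement,
                                harea$cube, config$outDir,
                                world@vocabulary)
  run$conservation <- conservationReport(run, world)
  class(run) <- "NfertRun"
  run
}

#' @export
print.NfertRun <- function(x, ...) {
  cat("NfertRun\n")
  print(x$conservation$summary, row.names = FALSE)
  if (length(x$log)) cat(length(x$log), "logged notice(s)\n")
  invisible(x)
}
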