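# Validation diagnostics: the country-wise relative difference against a
# reference rate series, and conservation audits of every pipeline contract.

#' Country-wise relative difference against a reference rate
#'
#' `Dif = (rate - reference) / rate * 100` (percent); the denominator is
#' always the reconstructed rate. Entries with `rate == 0` are undefined and
#' returned as `NA` (excluded from summaries).
#'
#' @param rate numeric vector/array of reconstructed rates.
#' @param reference numeric vector/array of reference rates (same shape).
#' @return numeric object of the same shape, percent differences.
#' @examples
#' relativeDifference(100, 50)  #  50
#' relativeDifference(50, 100)  # -100
#' @export
relativeDifference <- function(rate, reference) {
  out <- (rate - reference) / rate * 100
  out[rate == 0] <- NA_real_
  out
}

#' Mean/SD summary of relative differences by crop and region
#'
#' @param dif numeric array `crop x country x year` of percent differences
#'   (NAs excluded).
#' @param regionMap named character, country -> region.
#' @return data.frame with `crop`, `region`, `mean`, `sd`, `n`.
#' @export
difSummary <- function(dif, regionMap) {
  crops <- dimnames(dif)[[1]]
  countries <- dimnames(dif)[[2]]
  regs <- sort(unique(regionMap[countries]))
  out <- expand.grid(crop = crops, region = regs, stringsAsFactors = FALSE)
  out$mean <- out$sd <- NA_real_
  out$n <- 0L
  for (r in seq_len(nrow(out))) {
    js <- countries[regionMap[countries] == out$region[r]]
    vals <- dif[out$crop[r], js, ]
    vals <- vals[is.finite(vals)]
    out$n[r] <- length(vals)
    if (length(vals)) {
      out$mean[r] <- mean(vals)
      out$sd[r] <- stats::sd(vals)
    }
  }
  out
}

relErr <- function(have, want) {
  err <- abs(have - want) / ifelse(abs(want) > 0, abs(want), 1)
  err[want == 0 & have == 0] <- 0
  err
}

#' Conservation audits of a pipeline run
#'
#' Checks every exact-conservation contract of the reconstruction on a
#' completed [runPipeline()] result: gridded harvested area vs the national
#' series; county SN sums vs the national SN amounts (pre-calibration);
#' anchor-year crop-group SN amounts vs the FUBC table (post-calibration);
#' type-share sums vs 1; placement surface+deep sums vs 1. Every audit
#' reports its maximum relative error plus the offending table so corrupted
#' inputs can be localized.
#'
#' @param run a [runPipeline()] result.
#' @param world the [SyntheticWorld-class] the run consumed.
#' @return list with `summary` (data.frame check/maxRelErr) and per-check
#'   error tables under `details`.
#' @export
conservationReport <- function(run, world) {
  hier <- world@hierarchy
  vocab <- world@vocabulary
  cellsOf <- countyCells(hier)
  details <- list()

  # 1. gridded harvested area vs national series
  national <- run$harea$national
  cube <- run$harea$cube
  crops <- dimnames(cube@values)[[1]]
  yc <- dimnames(cube@values)[[2]]
  ctry <- cellCountry(hier)
  errH <- array(0, c(length(crops), length(hier@countries), length(yc)),
                dimnames = list(crops, hier@countries, yc))
  for (j in hier@countries) {
    sums <- rowSums(cube@values[, , which(ctry == j), drop = FALSE],
                    dims = 2L)
    want <- national[crops, j, yc]
    want[is.na(want)] <- 0
    errH[, j, ] <- relErr(sums, want)
  }
  details$hareaNational <- errH

  # 2. county SN sums vs (cropland-use corrected) national SN
  namount <- run$napp$namount
  frac <- world@covariatePanel$croplandUseFraction
  errSN <- matrix(0, length(hier@countries), length(yc),
                  dimnames = list(hier@countries, yc))
  for (j in hier@countries) {
    cnt <- countiesOf(hier, j)
    have <- colSums(matrix(namount["SN", cnt, yc], ncol = length(yc)))
    want <- world@faoNamountSeries["SN", j, yc] * frac[j]
    want[is.na(want)] <- 0
    errSN[j, ] <- relErr(have, want)
  }
  details$snNational <- errSN

  # 3. anchor-year crop-group SN amounts vs FUBC
  anchors <- dimnames(world@fubcTables$anchors)[[3]]
  cro2 <- dimnames(world@fubcTables$anchors)[[1]]
  errF <- array(0, c(length(cro2), length(hier@countries), length(anchors)),
                dimnames = list(cro2, hier@countries, anchors))
  for (j in hier@countries) {
    cnt <- countiesOf(hier, j)
    for (a in anchors) {
      amt <- matrix(run$napp$rates[, "SN", cnt, a], nrow = length(crops)) *
        matrix(run$harea$county[, cnt, a], nrow = length(crops))
      grp <- rowsum(rowSums(amt), vocab$cropToFubc[crops])
      want <- world@fubcTables$anchors[, j, a]
      have <- stats::setNames(rep(0, length(cro2)), cro2)
      have[rownames(grp)] <- grp[, 1]
      # groups that could not be calibrated (zero denominator) are excluded
      ok <- have > 0 | want == 0
      errF[ok, j, a] <- relErr(have[ok], want[ok])
    }
  }
  details$fubcAnchors <- errF

  # 4. type shares sum to 1 where the county total amount is positive
  county <- run$shares@county
  total <- colSums(namount)
  s <- colSums(county)                                # county x year
  errT <- abs(s - 1)
  errT[total <= 0] <- abs(s[total <= 0])
  details$typeShareSum <- errT

  # 5. placement surface + deep = 1 for every fertilizer type
  pc <- run$placement$placement
  errP <- vapply(vocab$fertilizerTypes, function(f)
    max(abs(placementDeep(pc, f) + placementSurface(pc, f) - 1)),
    numeric(1))
  details$placementSum <- errP

  summary <- data.frame(
    check = c("harea_vs_national", "sn_vs_national", "fubc_anchor_groups",
              "type_share_sum", "placement_sum"),
    maxRelErr = c(max(errH), max(errSN), max(errF), max(errT), max(errP)))
  list(summary = summary, details = details)
}
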