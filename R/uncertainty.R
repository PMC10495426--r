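# Monte Carlo uncertainty of crop-specific rates: the year-to-year change
# ratios of each crop-region trajectory are perturbed with mean-1 normal
# draws whose SD is the coefficient of variation estimated from the five
# FUBC anchor years, and the trajectory is rebuilt from the year-2000 anchor.

#' Estimate crop-group coefficients of variation from FUBC anchor years
#'
#' Per FUBC crop group and region, the mean, sample standard deviation
#' (n - 1 denominator) and CV of the group's fertilizer use across the anchor
#' years (2006, 2007, 2010, 2014, 2018). Entries with zero mean have an
#' undefined CV and are flagged (`NA`).
#'
#' @param fubc list with `anchors`: numeric array `cro2 x country x anchorYear`.
#' @param regionMap named character, country -> region.
#' @return data.frame with columns `group`, `region`, `mean`, `sd`, `cv`.
#' @examples
#' a <- array(c(80, 90, 100, 110, 120), c(1, 1, 5),
#'            dimnames = list("Wheat", "C01", 2006 + 0:4))
#' estimateCvFromFubc(list(anchors = a), c(C01 = "R1"))
#' @export
estimateCvFromFubc <- function(fubc, regionMap) {
  anchors <- fubc$anchors
  groups <- dimnames(anchors)[[1]]
  countries <- dimnames(anchors)[[2]]
  regs <- sort(unique(regionMap[countries]))
  out <- expand.grid(group = groups, region = regs,
                     stringsAsFactors = FALSE)
  out$mean <- out$sd <- out$cv <- NA_real_
  for (r in seq_len(nrow(out))) {
    js <- countries[regionMap[countries] == out$region[r]]
    vals <- apply(anchors[out$group[r], js, , drop = FALSE], 3, sum)
    mu <- mean(vals)
    s <- stats::sd(vals)
    out$mean[r] <- mu
    out$sd[r] <- s
    out$cv[r] <- if (mu > 0) s / mu else NA_real_
  }
  out
}

#' Area-weighted regional mean rate trajectories
#'
#' Collapses county crop rates to crop x region x year trajectories using
#' harvested areas as weights — the input [monteCarloRates()] perturbs.
#'
#' @param rates numeric array `crop x class x county x year`.
#' @param hareaCounty numeric array `crop x county x year`.
#' @param hierarchy an [AdminHierarchy-class].
#' @param regionMap named character, country -> region (defaults to the
#'   hierarchy's reporting regions).
#' @param class which input class to summarize (default total over classes).
#' @return numeric array `crop x region x year` (kg N/ha).
#' @export
regionalRates <- function(rates, hareaCounty, hierarchy,
                          regionMap = hierarchy@regions, class = NULL) {
  crops <- dimnames(rates)[[1]]
  counties <- dimnames(rates)[[3]]
  yc <- dimnames(rates)[[4]]
  rate <- if (is.null(class)) {
    apply(rates, c(1, 3, 4), sum)
  } else rates[, class, , , drop = TRUE]
  regs <- sort(unique(regionMap))
  out <- array(0, c(length(crops), length(regs), length(yc)),
               dimnames = list(crops, regs, yc))
  ctyReg <- regionMap[hierarchy@countyCountry[counties]]
  for (m in regs) {
    cnt <- counties[ctyReg == m]
    w <- hareaCounty[, cnt, yc, drop = FALSE]
    num <- apply(rate[, cnt, , drop = FALSE] * w, c(1, 3), sum)
    den <- apply(w, c(1, 3), sum)
    out[, m, ] <- num / ifelse(den > 0, den, 1)
  }
  out
}

#' Monte Carlo uncertainty envelopes for rate trajectories
#'
#' For each crop-region trajectory, every year-to-year change ratio is
#' multiplied by an independent normal draw with mean 1 and SD equal to the
#' group-region CV (truncated at 0 so rates stay non-negative), and the
#' trajectory is rebuilt outward from the year-2000 anchor in both
#' directions. Percentile envelopes (2.5/97.5) and SDs are computed across
#' iterations. A missing CV leaves the envelope degenerate at the point
#' estimate (flagged).
#'
#' @param rates numeric array `crop x region x year` (see [regionalRates()]).
#' @param cvTable data.frame from [estimateCvFromFubc()].
#' @param vocabulary the vocabulary list (crop -> FUBC group map).
#' @param nIter number of Monte Carlo iterations (>= 2; 1000 by default).
#' @param seed integer seed.
#' @param anchorYear year held fixed while ratios are perturbed (2000).
#' @return list of class `UncertaintyEnvelope` with arrays `point`, `mean`,
#'   `sd`, `lower`, `upper` (`crop x region x year`) and `nIter`.
#' @export
monteCarloRates <- function(rates, cvTable, vocabulary, nIter = 1000L,
                            seed = 1L, anchorYear = 2000L) {
  stopifnot(nIter >= 2L)
  set.seed(seed)
  crops <- dimnames(rates)[[1]]
  regs <- dimnames(rates)[[2]]
  yrs <- as.integer(dimnames(rates)[[3]])
  aIdx <- which(yrs == anchorYear)
  if (!length(aIdx)) stop("anchor year not in the trajectory", call. = FALSE)
  dims <- dim(rates)
  point <- rates
  mcMean <- mcSd <- lower <- upper <- array(0, dims, dimnames = dimnames(rates))
  missingCv <- FALSE
  for (cro in crops) for (m in regs) {
    grp <- vocabulary$cropToFubc[cro]
    cv <- cvTable$cv[cvTable$group == grp & cvTable$region == m]
    cv <- if (length(cv)) cv[1] else NA_real_
    traj <- rates[cro, m, ]
    if (!is.finite(cv)) {
      missingCv <- TRUE
      mcMean[cro, m, ] <- traj
      lower[cro, m, ] <- traj
      upper[cro, m, ] <- traj
      next
    }
    sims <- simulateTrajectories(traj, cv, nIter, aIdx)
    mcMean[cro, m, ] <- colMeans(sims)
    mcSd[cro, m, ] <- apply(sims, 2, stats::sd)
    qs <- apply(sims, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    lower[cro, m, ] <- qs[1, ]
    upper[cro, m, ] <- qs[2, ]
  }
  if (missingCv)
    warning("missing CV for some crop-region; envelope degenerates to the ",
            "point estimate", call. = FALSE)
  structure(list(point = point, mean = mcMean, sd = mcSd, lower = lower,
                 upper = upper, nIter = as.integer(nIter)),
            class = "UncertaintyEnvelope")
}

# nIter perturbed trajectories (rows) for one point trajectory. Every
# year-to-year change ratio gets multiplicative mean-1 normal noise truncated
# at 0; years after the anchor are rebuilt with perturbed forward ratios,
# years before it with perturbed backward ratios (so the expectation stays at
# the point estimate on both sides — dividing by a mean-1 draw would bias the
# pre-anchor years upward).
simulateTrajectories <- function(traj, cv, nIter, anchorIdx) {
  ny <- length(traj)
  sims <- matrix(0, nIter, ny)
  sims[, anchorIdx] <- traj[anchorIdx]
  if (ny == 1L) return(sims)
  fwd <- traj[-1] / traj[-ny]
  fwd[!is.finite(fwd)] <- 1                           # 0 -> 0 transitions
  bwd <- traj[-ny] / traj[-1]
  bwd[!is.finite(bwd)] <- 1
  noise <- matrix(pmax(0, stats::rnorm(nIter * (ny - 1), 1, cv)),
                  nIter, ny - 1L)
  if (anchorIdx < ny)
    for (k in (anchorIdx + 1):ny)
      sims[, k] <- sims[, k - 1] * fwd[k - 1] * noise[, k - 1]
  if (anchorIdx > 1L)
    for (k in (anchorIdx - 1):1)
      sims[, k] <- sims[, k + 1] * bwd[k] * noise[, k]
  sims
}

#' @export
print.UncertaintyEnvelope <- function(x, ...) {
  cat(sprintf("UncertaintyEnvelope: %d crops x %d regions x %d years, %d iterations\n",
              dim(x$point)[1], dim(x$point)[2], dim(x$point)[3], x$nIter))
  invisible(x)
}
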