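# Fertilizer-type shares: impute the missing cells of the time-series
# cross-section consumption panel with a bootstrap-EM multivariate-normal
# model, then convert consumption mixes plus class amounts into 13-way shares.

# --- EM for a multivariate normal with missing data --------------------------
# Rows are observations, columns variables. Returns list(mu, sigma).
emNorm <- function(X, maxit = 100L, tol = 1e-6, ridge = 1e-6) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  sigma <- stats::cov(X, use = "pairwise.complete.obs")
  sigma[!is.finite(sigma)] <- 0
  diag(sigma) <- pmax(diag(sigma), 1e-4)
  miss <- is.na(X)
  patterns <- apply(miss, 1, function(r) paste(which(r), collapse = ","))
  rowsByPattern <- split(seq_len(n), patterns)
  for (it in seq_len(maxit)) {
    Xhat <- X
    S <- matrix(0, p, p)
    for (pat in names(rowsByPattern)) {
      rows <- rowsByPattern[[pat]]
      m <- if (nzchar(pat)) as.integer(strsplit(pat, ",")[[1]]) else integer()
      o <- setdiff(seq_len(p), m)
      if (length(m)) {
        if (length(o)) {
          Soo <- sigma[o, o, drop = FALSE]
          diag(Soo) <- diag(Soo) + ridge * mean(diag(sigma))
          B <- sigma[m, o, drop = FALSE] %*% solve(Soo)
          resid <- sweep(X[rows, o, drop = FALSE], 2, mu[o])
          Xhat[rows, m] <- matrix(mu[m], length(rows), length(m),
                                  byrow = TRUE) + resid %*% t(B)
          condVar <- sigma[m, m, drop = FALSE] -
            B %*% sigma[o, m, drop = FALSE]
        } else {
          Xhat[rows, m] <- matrix(mu[m], length(rows), length(m),
                                  byrow = TRUE)
          condVar <- sigma[m, m, drop = FALSE]
        }
        S[m, m] <- S[m, m] + length(rows) * condVar
      }
    }
    muNew <- colMeans(Xhat)
    Xc <- sweep(Xhat, 2, muNew)
    sigmaNew <- (crossprod(Xc) + S) / n
    diag(sigmaNew) <- pmax(diag(sigmaNew), 1e-8)
    delta <- max(abs(sigmaNew - sigma)) + max(abs(muNew - mu))
    mu <- muNew; sigma <- sigmaNew
    if (delta < tol) break
  }
  list(mu = mu, sigma = sigma, imputed = Xhat)
}

# One conditional draw of the missing entries of X under (mu, sigma).
drawMissing <- function(X, mu, sigma, ridge = 1e-6) {
  p <- ncol(X)
  out <- X
  for (r in seq_len(nrow(X))) {
    m <- which(is.na(X[r, ]))
    if (!length(m)) next
    o <- setdiff(seq_len(p), m)
    if (length(o)) {
      Soo <- sigma[o, o, drop = FALSE]
      diag(Soo) <- diag(Soo) + ridge * mean(diag(sigma))
      B <- sigma[m, o, drop = FALSE] %*% solve(Soo)
      cm <- mu[m] + as.vector(B %*% (X[r, o] - mu[o]))
      cv <- sigma[m, m, drop = FALSE] - B %*% sigma[o, m, drop = FALSE]
    } else {
      cm <- mu[m]
      cv <- sigma[m, m, drop = FALSE]
    }
    cv <- (cv + t(cv)) / 2
    ev <- eigen(cv, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(m))
    out[r, m] <- cm + as.vector(L %*% stats::rnorm(length(m)))
  }
  out
}

#' Impute missing fertilizer-type consumption
#'
#' Missing cells of the type-consumption panel are filled with the mean of
#' `m` draws from a bootstrap-EM multivariate-normal model fitted on
#' log-transformed consumption (offset 1), the observed total SN consumption,
#' log-transformed covariates (GDP, population, cropland area aggregated to
#' the reporting unit) and linear plus quadratic time terms. Observed cells
#' are never touched; imputed values are clamped at zero. Reporting units
#' with fewer than three observed years for some consumption series fall back
#' to within-unit linear interpolation/extrapolation (flagged).
#'
#' @param panel list with `values` (snType x region x year, kg N, NA =
#'   missing), `totalSn` (region x year) and `missingMask`.
#' @param covariates list with `gdp`, `population`, `croplandArea`
#'   (country x year matrices).
#' @param hierarchy an [AdminHierarchy-class] (for the country -> region map).
#' @param m number of imputation draws averaged (default 5).
#' @param seed integer seed for the bootstrap and the conditional draws.
#' @return The panel with `values` completed (no NAs).
#' @export
imputeMissingConsumption <- function(panel, covariates, hierarchy, m = 5L,
                                     seed = 1L) {
  vals <- panel$values
  if (!anyNA(vals)) return(panel)
  set.seed(seed)
  types <- dimnames(vals)[[1]]
  regs <- dimnames(vals)[[2]]
  yrs <- as.integer(dimnames(vals)[[3]])
  ny <- length(yrs)
  regionOf <- hierarchy@regions
  aggReg <- function(M) {
    # country x year -> region x year sums
    rowsum(M[names(regionOf), , drop = FALSE], regionOf)[regs, ,
                                                         drop = FALSE]
  }
  gdp <- aggReg(covariates$gdp)
  popn <- aggReg(covariates$population)
  cla <- aggReg(covariates$croplandArea)

  tScaled <- (yrs - mean(yrs)) / stats::sd(yrs)
  filled <- vals
  for (mIdx in seq_along(regs)) {
    reg <- regs[mIdx]
    Y <- t(vals[, reg, ])                            # year x type
    obsCount <- colSums(!is.na(Y))
    if (min(obsCount) < 3L) {
      warning("reporting unit ", reg, " has a series with < 3 observed ",
              "years; using linear interpolation fallback", call. = FALSE)
      for (f in types) {
        y <- vals[f, reg, ]
        if (all(is.na(y))) { filled[f, reg, ] <- 0; next }
        ok <- which(!is.na(y))
        filled[f, reg, ] <- pmax(0, stats::approx(yrs[ok], y[ok], xout = yrs,
                                                  rule = 2)$y)
      }
      next
    }
    X <- cbind(log1p(Y),
               totalSn = log1p(panel$totalSn[reg, ]),
               gdp = log1p(gdp[reg, ]), pop = log1p(popn[reg, ]),
               cropland = log1p(cla[reg, ]), t = tScaled, t2 = tScaled^2)
    draws <- matrix(0, ny, length(types))
    for (b in seq_len(m)) {
      boot <- X[sample.int(ny, ny, replace = TRUE), , drop = FALSE]
      fit <- emNorm(boot)
      Xd <- drawMissing(X, fit$mu, fit$sigma)
      draws <- draws + Xd[, seq_along(types), drop = FALSE]
    }
    imputedY <- matrix(pmax(0, expm1(draws / m)), ny, length(types))
    obs <- !is.na(Y)
    imputedY[obs] <- Y[obs]
    filled[, reg, ] <- t(imputedY)
  }
  panel$values <- filled
  panel
}

#' Compute 13-way fertilizer-type shares and rasterize them
#'
#' Crop-residue and manure shares are their class amount over the total
#' amount; each synthetic type's share is its fraction of the reporting
#' unit's SN consumption mix times the SN fraction of the total amount.
#' Component mixes are normalized by the sum of the 11 components, so shares
#' sum to exactly 1 wherever the total amount is positive. A reporting unit
#' with zero consumption across all components in a year routes the SN mass
#' to urea as the default carrier (flagged).
#'
#' @param panel imputed type-consumption panel (see
#'   [imputeMissingConsumption()]).
#' @param namount numeric array `class x county x year` (kg N).
#' @param hierarchy an [AdminHierarchy-class].
#' @param grid the [GridDefinition-class].
#' @param vocabulary the vocabulary list.
#' @return A [TypeShareCube-class] (grid values plus the county-level table).
#' @export
computeTypeShares <- function(panel, namount, hierarchy, grid, vocabulary) {
  types <- vocabulary$fertilizerTypes
  snTypes <- vocabulary$snTypes
  counties <- dimnames(namount)[[2]]
  yc <- dimnames(namount)[[3]]
  county <- array(0, c(length(types), length(counties), length(yc)),
                  dimnames = list(types, counties, yc))
  total <- colSums(namount)                           # county x year
  pos <- total > 0
  ureaFallback <- FALSE
  mixCache <- list()
  for (i in counties) {
    m <- hierarchy@regions[hierarchy@countyCountry[i]]
    if (is.null(mixCache[[m]])) {
      comp <- matrix(panel$values[snTypes, m, yc],
                     nrow = length(snTypes), dimnames = list(snTypes, yc))
      s <- colSums(comp)
      mix <- sweep(comp, 2, ifelse(s > 0, s, 1), "/")
      if (any(s <= 0)) {
        mix[, s <= 0] <- 0
        mix["Urea", s <= 0] <- 1
        ureaFallback <- TRUE
      }
      mixCache[[m]] <- mix                            # snType x year
    }
    mix <- mixCache[[m]]
    tot <- ifelse(pos[i, ], total[i, ], 1)
    county["CR", i, ] <- ifelse(pos[i, ], namount["CR", i, ] / tot, 0)
    county["MA", i, ] <- ifelse(pos[i, ], namount["MA", i, ] / tot, 0)
    snFrac <- ifelse(pos[i, ], namount["SN", i, ] / tot, 0)
    county[snTypes, i, ] <- mix * rep(snFrac, each = length(snTypes))
  }
  if (ureaFallback)
    warning("zero type-consumption sum with positive SN amount; ",
            "SN mass assigned to urea", call. = FALSE)
  vals <- array(0, c(length(types), length(yc), nCells(grid)),
                dimnames = list(types, yc, cellIds(grid)))
  cellsOf <- countyCells(hierarchy)
  for (i in counties) {
    cells <- cellsOf[[i]]
    if (length(cells)) vals[, , cells] <- county[, i, ]
  }
  new("TypeShareCube", values = vals, county = county, grid = grid,
      years = as.integer(yc))
}
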