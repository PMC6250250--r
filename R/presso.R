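#' @include AllClasses.R AllGenerics.R utils.R estimators.R
NULL

## Leave-one-out IVW slopes from ratio vectors (theta, w), computed from the
## running totals so a whole simulation replicate costs O(J).
.looSlopes <- function(theta, w) {
  (sum(w * theta) - w * theta) / (sum(w) - w)
}

## Per-SNP weights on matrices (nSim x J) for the simulation replicates.
.waldWeightMatrix <- function(BX, BY, sx2, sy2, seOrder) {
  if (seOrder == "first") {
    BX^2 / matrix(sy2, nrow(BX), ncol(BX), byrow = TRUE)
  } else {
    SX2 <- matrix(sx2, nrow(BX), ncol(BX), byrow = TRUE)
    SY2 <- matrix(sy2, nrow(BX), ncol(BX), byrow = TRUE)
    1 / (SY2 / BX^2 + BY^2 * SX2 / BX^4)
  }
}

#' @describeIn mrPresso residual-sum-and-outlier test. For each SNP the
#'   observed residual from the leave-one-out zero-intercept IVW fit is
#'   summarized as `RSS_j = w_j (betaY_j - theta_(-j) betaX_j)^2`; the global
#'   statistic `sum RSS_j` is compared with its distribution under `nSim`
#'   parametric replicates drawn without pleiotropy
#'   (`betaX* ~ N(betaX, seX)`, `betaY* ~ N(theta_(-j) betaX, seY)`, with the
#'   full statistic recomputed per replicate). Per-SNP outlier p-values are
#'   empirical tail probabilities, Bonferroni-multiplied by J; empirical
#'   p-values use the add-one rule so they are never zero. When outliers are
#'   found, the IVW estimate is recomputed without them and a distortion test
#'   compares the induced shift against removal of random subsets of the same
#'   size. The residual weights default to first-order (outcome-variance)
#'   Wald weights, the original residual-sum formulation: a second-order
#'   weight would let a pleiotropic SNP's own inflated outcome effect enter
#'   its weight denominator and mask it from the very test meant to find it.
setMethod("mrPresso", "InstrumentSet",
          function(x, nSim = 1000, seed = NULL, outlierAlpha = 0.05,
                   seOrder = c("first", "second")) {
  seOrder <- match.arg(seOrder, c("first", "second"))
  df <- x@instruments
  J <- nrow(df)
  if (J < 4) stop("MR-PRESSO requires at least 4 instruments, got ", J)
  if (nSim < 1000) stop("nSim must be at least 1000")

  r <- waldRatios(x, seOrder)
  w <- r$weight
  th <- r$theta
  thLoo <- .looSlopes(th, w)
  resid <- df$beta_y - thLoo * df$beta_x
  rssj <- w * resid^2
  rssObs <- sum(rssj)
  estimateRaw <- .ivwFromRatios(r, seOrder, method = "presso_raw")

  out <- withSeed(seed, {
    BX <- matrix(stats::rnorm(nSim * J, mean = df$beta_x, sd = df$se_x),
                 nSim, J, byrow = TRUE)
    BY <- matrix(stats::rnorm(nSim * J, mean = thLoo * df$beta_x, sd = df$se_y),
                 nSim, J, byrow = TRUE)
    TH <- BY / BX
    W <- .waldWeightMatrix(BX, BY, df$se_x^2, df$se_y^2, seOrder)
    WT <- W * TH
    thLooS <- (rowSums(WT) - WT) / (rowSums(W) - W)
    RSSJ <- W * (BY - thLooS * BX)^2
    rssSim <- rowSums(RSSJ)
    globalPval <- (1 + sum(rssSim >= rssObs)) / (nSim + 1)
    exceed <- colSums(RSSJ >= matrix(rssj, nSim, J, byrow = TRUE))
    pRaw <- (1 + exceed) / (nSim + 1)
    pAdj <- pmin(1, pRaw * J)
    names(pAdj) <- df$rsid
    outliers <- df$rsid[pAdj < outlierAlpha]

    estimateCorrected <- NULL
    distortionPval <- NA_real_
    if (length(outliers) == J)
      stop("all instruments flagged as outliers: ",
           "fewer than 50% valid instruments assumption violated")
    if (length(outliers)) {
      keep <- !(df$rsid %in% outliers)
      estimateCorrected <- .ivwFromRatios(r[keep, ], seOrder,
                                          method = "presso_outlier_corrected")
      k <- length(outliers)
      bRaw <- mrBeta(estimateRaw)
      bCor <- mrBeta(estimateCorrected)
      dObs <- (bRaw - bCor) / bCor
      idx <- matrix(replicate(nSim, sample.int(J, k)), nrow = k)
      wth <- w * th
      bSub <- (sum(wth) - colSums(matrix(wth[idx], nrow = k))) /
        (sum(w) - colSums(matrix(w[idx], nrow = k)))
      dStar <- (bRaw - bSub) / bSub
      distortionPval <- (1 + sum(abs(dStar) >= abs(dObs))) / (nSim + 1)
    }
    list(globalPval = globalPval, pAdj = pAdj, outliers = outliers,
         estimateCorrected = estimateCorrected,
         distortionPval = distortionPval)
  })

  new("PressoResult", globalRSS = rssObs, globalPval = out$globalPval,
      outlierPvals = out$pAdj, outliers = out$outliers,
      estimateRaw = estimateRaw, estimateCorrected = out$estimateCorrected,
      distortionPval = out$distortionPval, nSim = as.integer(nSim),
      settings = list(seed = seed, outlierAlpha = outlierAlpha,
                      seOrder = seOrder))
})
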