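#' @include AllClasses.R AllGenerics.R utils.R wald.R
NULL

## ---- fixed-effect IVW ------------------------------------------------------

.ivwFromRatios <- function(ratios, seOrder, method = "ivw_fixed") {
  ratios <- .checkRatios(ratios, minSnps = 1L, caller = "mrIVW")
  w <- ratios$weight
  beta <- sum(w * ratios$theta) / sum(w)
  se <- sum(w)^-0.5
  .newMREstimate(method, beta, se, nrow(ratios), seOrder)
}

#' @describeIn mrIVW pool the Wald ratios of an instrument set with
#'   fixed-effect inverse-variance weighting: `beta = sum(w theta)/sum(w)`,
#'   `se = sum(w)^-1/2`, normal-reference CI and p-value.
setMethod("mrIVW", "InstrumentSet",
          function(x, seOrder = c("second", "first"), method = "ivw_fixed") {
  seOrder <- .matchSeOrder(seOrder)
  .ivwFromRatios(waldRatios(x, seOrder), seOrder, method)
})

#' @describeIn mrIVW pool a precomputed Wald-ratio table (columns `theta`,
#'   `se`, optional `weight`).
setMethod("mrIVW", "data.frame",
          function(x, seOrder = "second", method = "ivw_fixed") {
  .ivwFromRatios(x, seOrder, method)
})

## ---- MR-Egger --------------------------------------------------------------

## Weighted least squares of betaY on betaX (free intercept) after orienting
## every SNP so betaX > 0. Regression weights are the Wald-ratio weights
## divided by betaX^2, so the zero-intercept constrained fit coincides with
## the IVW estimate under the same se order.
.eggerFit <- function(x, seOrder) {
  df <- x@instruments
  J <- nrow(df)
  if (J < 3) stop("MR-Egger requires at least 3 instruments, got ", J)
  s <- sign(df$beta_x)
  bx <- df$beta_x * s
  by <- df$beta_y * s
  r <- waldRatios(x, seOrder)  # theta, se invariant to orientation
  v <- r$weight / bx^2
  sw <- sum(v); swx <- sum(v * bx); swy <- sum(v * by)
  swxx <- sum(v * bx^2); swxy <- sum(v * bx * by)
  den <- sw * swxx - swx^2
  if (!is.finite(den) || den <= .Machine$double.eps * sw * swxx)
    stop("singular design in MR-Egger: no spread in exposure effects")
  slope <- (sw * swxy - swx * swy) / den
  inter <- (swy - slope * swx) / sw
  res <- by - inter - slope * bx
  qPrime <- sum(v * res^2)
  list(slope = slope, intercept = inter, qPrime = qPrime, J = J,
       varSlopeUnit = sw / den, varInterUnit = swxx / den,
       weights = v, bx = bx, by = by)
}

#' @describeIn mrEgger weighted linear regression of the oriented SNP-outcome
#'   effects on the SNP-exposure effects with a free intercept. The slope is
#'   the pleiotropy-adjusted causal estimate; the intercept estimates
#'   directional pleiotropy (no evidence when its p-value is >= 0.05).
#'   Inference uses a t reference on J-2 df with standard errors inflated by
#'   `max(1, sqrt(Q'/(J-2)))` (multiplicative random-effects convention).
setMethod("mrEgger", "InstrumentSet",
          function(x, seOrder = c("second", "first")) {
  seOrder <- .matchSeOrder(seOrder)
  fit <- .eggerFit(x, seOrder)
  disp <- max(1, fit$qPrime / (fit$J - 2))
  seSlope <- sqrt(disp * fit$varSlopeUnit)
  seInter <- sqrt(disp * fit$varInterUnit)
  pInter <- 2 * stats::pt(-abs(fit$intercept / seInter), fit$J - 2)
  .newMREstimate("egger", fit$slope, seSlope, fit$J, seOrder, df = fit$J - 2,
                 extras = list(intercept = fit$intercept,
                               interceptSE = seInter,
                               interceptPval = pInter,
                               qPrime = fit$qPrime,
                               overdispersion = disp,
                               inference = "t(J-2), multiplicative overdispersion floored at 1"))
})

## ---- weighted median -------------------------------------------------------

## Interpolated weighted median: order theta ascending, standardized
## cumulative weights p_j = (S_j - w_j/2)/S_J, linear interpolation at 0.5.
.weightedMedianPoint <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  ww <- w[o]
  p <- (cumsum(ww) - ww / 2) / sum(ww)
  J <- length(th)
  if (p[1] >= 0.5) return(th[1])
  if (p[J] <= 0.5) return(th[J])
  stats::approx(p, th, xout = 0.5, ties = "ordered")$y
}

.parametricBootstrapSE <- function(theta, se, w, nBoot, seed, pointFun) {
  J <- length(theta)
  withSeed(seed, {
    draws <- matrix(stats::rnorm(nBoot * J, mean = theta, sd = se),
                    nrow = nBoot, byrow = TRUE)
    reps <- apply(draws, 1L, pointFun, w = w)
    stats::sd(reps)
  })
}

.weightedMedianFromRatios <- function(ratios, nBoot, seed, seOrder) {
  ratios <- .checkRatios(ratios, minSnps = 3L, caller = "mrWeightedMedian")
  if (nBoot < 100) stop("nBoot must be at least 100")
  est <- .weightedMedianPoint(ratios$theta, ratios$weight)
  se <- .parametricBootstrapSE(ratios$theta, ratios$se, ratios$weight,
                               nBoot, seed, .weightedMedianPoint)
  .newMREstimate("weighted_median", est, se, nrow(ratios), seOrder,
                 extras = list(nBoot = nBoot, seed = seed))
}

#' @describeIn mrWeightedMedian weighted median of the per-SNP Wald ratios:
#'   ratios are ranked, cumulative weights standardized to
#'   `(S_j - w_j/2)/S_J`, and the estimate interpolated at probability 0.5.
#'   The SE is the standard deviation of the estimator over `nBoot`
#'   parametric-bootstrap replicates (each ratio redrawn from
#'   `N(theta_j, se_j)`); CI = estimate +/- 1.96 SE. Consistent when valid
#'   instruments contribute more than half the weight.
setMethod("mrWeightedMedian", "InstrumentSet",
          function(x, nBoot = 1000, seed = NULL,
                   seOrder = c("second", "first")) {
  seOrder <- .matchSeOrder(seOrder)
  .weightedMedianFromRatios(waldRatios(x, seOrder), nBoot, seed, seOrder)
})

#' @describeIn mrWeightedMedian on a precomputed Wald-ratio table.
setMethod("mrWeightedMedian", "data.frame",
          function(x, nBoot = 1000, seed = NULL, seOrder = "second") {
  .weightedMedianFromRatios(x, nBoot, seed, seOrder)
})

## ---- weighted mode ---------------------------------------------------------

## Mode of a weighted normal-kernel density of the ratios. Bandwidth is the
## normal-reference rule h = phi * 0.9 * min(sd, mad) * J^(-1/5) (mad with
## the consistency constant 1.4826), evaluated on a 512-point grid spanning
## [min - 3h, max + 3h].
.weightedModePoint <- function(theta, w, phi = 1, gridN = 512L) {
  if (diff(range(theta)) < .Machine$double.eps^0.5) return(theta[1])
  s <- min(stats::sd(theta), stats::mad(theta))
  if (s <= 0) s <- stats::sd(theta)
  h <- phi * 0.9 * s * length(theta)^(-1 / 5)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = gridN)
  ww <- w / sum(w)
  dens <- colSums(ww * exp(-0.5 * ((outer(theta, grid, "-")) / h)^2))
  grid[which.max(dens)]
}

.weightedModeFromRatios <- function(ratios, phi, nBoot, seed, seOrder) {
  ratios <- .checkRatios(ratios, minSnps = 3L, caller = "mrWeightedMode")
  if (phi <= 0) stop("phi must be positive")
  if (nBoot < 100) stop("nBoot must be at least 100")
  point <- function(theta, w) .weightedModePoint(theta, w, phi = phi)
  est <- point(ratios$theta, ratios$weight)
  se <- .parametricBootstrapSE(ratios$theta, ratios$se, ratios$weight,
                               nBoot, seed, point)
  .newMREstimate("weighted_mode", est, se, nrow(ratios), seOrder,
                 extras = list(phi = phi, nBoot = nBoot, seed = seed,
                               gridN = 512L))
}

#' @describeIn mrWeightedMode the causal estimate is the maximizer of a
#'   weighted normal-kernel density of the per-SNP ratios, i.e. the value
#'   supported by the largest cluster of concordant SNPs (reliable when that
#'   cluster is valid). `phi` scales the normal-reference bandwidth
#'   (default 1); SE/CI via the same parametric bootstrap as the weighted
#'   median.
setMethod("mrWeightedMode", "InstrumentSet",
          function(x, phi = 1, nBoot = 1000, seed = NULL,
                   seOrder = c("second", "first")) {
  seOrder <- .matchSeOrder(seOrder)
  .weightedModeFromRatios(waldRatios(x, seOrder), phi, nBoot, seed, seOrder)
})

#' @describeIn mrWeightedMode on a precomputed Wald-ratio table.
setMethod("mrWeightedMode", "data.frame",
          function(x, phi = 1, nBoot = 1000, seed = NULL, seOrder = "second") {
  .weightedModeFromRatios(x, phi, nBoot, seed, seOrder)
})
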