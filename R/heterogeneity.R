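#' @include AllClasses.R AllGenerics.R utils.R estimators.R
NULL

.cochranFromRatios <- function(ratios, pooledBeta = NULL) {
  ratios <- .checkRatios(ratios, minSnps = 2L, caller = "cochranQ")
  if (is.null(pooledBeta))
    pooledBeta <- sum(ratios$weight * ratios$theta) / sum(ratios$weight)
  q <- sum(ratios$weight * (ratios$theta - pooledBeta)^2)
  df <- nrow(ratios) - 1
  pval <- stats::pchisq(q, df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  new("HeterogeneityResult", q = q, df = df, pval = pval, i2MR = i2,
      flagPleiotropy = (i2 > 25) && (pval < 0.05))
}

#' @describeIn cochranQ heterogeneity of the per-SNP Wald ratios around the
#'   pooled estimate: `Q = sum w_j (theta_j - beta)^2` on J-1 df, with
#'   `I2MR = max(0, (Q - df)/Q) * 100`. Excessive heterogeneity (I2MR > 25%
#'   with Q-derived p < 0.05) is flagged as indicative of pleiotropy.
setMethod("cochranQ", "InstrumentSet",
          function(x, pooledBeta = NULL, seOrder = c("second", "first")) {
  seOrder <- .matchSeOrder(seOrder)
  .cochranFromRatios(waldRatios(x, seOrder), pooledBeta)
})

#' @describeIn cochranQ on a precomputed Wald-ratio table.
setMethod("cochranQ", "data.frame",
          function(x, pooledBeta = NULL) .cochranFromRatios(x, pooledBeta))

#' @describeIn ruckerModelSelection Rucker Q' is the weighted residual sum of
#'   squares of the MR-Egger fit (same weights as the fit, J-2 df); Cochran Q
#'   is evaluated at the IVW estimate under identical weights, so Q >= Q'
#'   always. Q - Q' referred to chi-square(1) tests whether freeing the
#'   intercept buys a significantly better fit; if so MR-Egger is preferred.
setMethod("ruckerModelSelection", "InstrumentSet",
          function(x, seOrder = c("second", "first")) {
  seOrder <- .matchSeOrder(seOrder)
  fit <- .eggerFit(x, seOrder)
  ratios <- waldRatios(x, seOrder)
  het <- .cochranFromRatios(ratios)
  qPrime <- fit$qPrime
  dfPrime <- fit$J - 2
  qDiff <- max(het@q - qPrime, 0)
  pModel <- stats::pchisq(qDiff, 1, lower.tail = FALSE)
  new("EggerModelSelection", q = het@q, qPrime = qPrime, dfPrime = dfPrime,
      pQPrime = stats::pchisq(qPrime, dfPrime, lower.tail = FALSE),
      qMinusQPrime = qDiff, pModelTest = pModel,
      eggerPreferred = pModel < 0.05)
})

#' @describeIn i2GX heterogeneity between the SNP-exposure estimates
#'   (oriented so beta_x > 0, as used by the Egger fit) relative to their
#'   standard errors: `Q_GX = sum se_x^-2 (bx - bbar)^2` with `bbar` the
#'   inverse-variance weighted mean, and
#'   `I2GX = max(0, (Q_GX - (J-1))/Q_GX) * 100`. Values above 95% indicate
#'   low risk of measurement-error (NOME-violation) bias in MR-Egger.
setMethod("i2GX", "InstrumentSet", function(x) {
  df <- x@instruments
  J <- nrow(df)
  if (J < 2) stop("i2GX requires at least 2 instruments")
  bx <- abs(df$beta_x)
  w <- df$se_x^-2
  bbar <- sum(w * bx) / sum(w)
  q <- sum(w * (bx - bbar)^2)
  i2 <- if (q > 0) max(0, (q - (J - 1)) / q) * 100 else 0
  new("IGXResult", qGX = q, df = J - 1, i2GX = i2, lowBiasFlag = i2 > 95)
})
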