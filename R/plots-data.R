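#' @include AllClasses.R AllGenerics.R utils.R estimators.R
NULL

.funnelFromRatios <- function(ratios, pooledBeta = NULL) {
  ratios <- .checkRatios(ratios, minSnps = 1L, caller = "funnelData")
  if (is.null(pooledBeta))
    pooledBeta <- sum(ratios$weight * ratios$theta) / sum(ratios$weight)
  data.frame(rsid = ratios$rsid, theta = ratios$theta,
             precision = 1 / ratios$se, pooled = pooledBeta,
             stringsAsFactors = FALSE)
}

.radialFromRatios <- function(ratios) {
  ratios <- .checkRatios(ratios, minSnps = 1L, caller = "radialData")
  slope <- sum(ratios$weight * ratios$theta) / sum(ratios$weight)
  data.frame(rsid = ratios$rsid, sqrt_w = sqrt(ratios$weight),
             theta_sqrt_w = ratios$theta * sqrt(ratios$weight),
             slope = slope, stringsAsFactors = FALSE)
}

#' @describeIn funnelData per-SNP ratio against precision, with the pooled
#'   IVW estimate as the reference line; asymmetry suggests directional
#'   pleiotropy.
setMethod("funnelData", "InstrumentSet",
          function(x, pooledBeta = NULL, seOrder = c("second", "first")) {
  seOrder <- .matchSeOrder(seOrder)
  .funnelFromRatios(waldRatios(x, seOrder), pooledBeta)
})

#' @describeIn funnelData on a precomputed Wald-ratio table.
setMethod("funnelData", "data.frame",
          function(x, pooledBeta = NULL) .funnelFromRatios(x, pooledBeta))

#' @describeIn radialData per-SNP contribution `theta_j sqrt(w_j)` against
#'   `sqrt(w_j)`; the through-origin slope of these points is exactly the IVW
#'   estimate, included as the `slope` reference column.
setMethod("radialData", "InstrumentSet",
          function(x, seOrder = c("second", "first")) {
  seOrder <- .matchSeOrder(seOrder)
  .radialFromRatios(waldRatios(x, seOrder))
})

#' @describeIn radialData on a precomputed Wald-ratio table.
setMethod("radialData", "data.frame", function(x) .radialFromRatios(x))

#' Render funnel / radial plots
#'
#' Presentation helpers over [funnelData()] and [radialData()]; the data
#' tables are the tested surface. Requires ggplot2.
#'
#' @param x an [InstrumentSet-class] or Wald-ratio data.frame.
#' @param ... passed to the data functions.
#' @return a ggplot object.
#' @export
plotFunnel <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- funnelData(x, ...)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$theta, y = .data$precision)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = d$pooled[1], linetype = 2) +
    ggplot2::labs(x = "Wald ratio (log-OR per SD)", y = "precision (1/SE)")
}

#' @rdname plotFunnel
#' @export
plotRadial <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- radialData(x, ...)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sqrt_w, y = .data$theta_sqrt_w)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = d$slope[1], intercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(sqrt(w[j])),
                  y = expression(theta[j] * sqrt(w[j])))
}
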