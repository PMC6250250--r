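#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname instruments
setMethod("instruments", "InstrumentSet", function(x) x@instruments)

#' @rdname instruments
setMethod("exposureLabel", "InstrumentSet", function(x) x@exposureLabel)

#' @rdname instruments
setMethod("outcomeLabel", "InstrumentSet", function(x) x@outcomeLabel)

#' @rdname instruments
setMethod("provenance", "InstrumentSet", function(x) x@provenance)

#' @describeIn instruments number of instruments in the set.
#' @export
setMethod("length", "InstrumentSet", function(x) nrow(x@instruments))

#' Subset an InstrumentSet
#'
#' @param x an [InstrumentSet-class].
#' @param i numeric/logical index or character rsIDs.
#' @param j,...,drop ignored.
#' @return the subsetted [InstrumentSet-class].
#' @export
setMethod("[", "InstrumentSet", function(x, i, j, ..., drop = FALSE) {
  df <- x@instruments
  if (is.character(i)) i <- match(i, df$rsid)
  if (anyNA(i)) stop("unknown rsid in subset")
  initialize(x, instruments = df[i, , drop = FALSE])
})

#' @describeIn instruments coerce to the underlying data.frame.
#' @param row.names,optional,... passed on.
#' @export
as.data.frame.InstrumentSet <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  df <- x@instruments
  rownames(df) <- row.names
  df
}

setMethod("show", "InstrumentSet", function(object) {
  df <- object@instruments
  cat(sprintf("InstrumentSet: %d instruments\n", nrow(df)))
  cat(sprintf("  exposure: %s (SD units)\n", object@exposureLabel))
  cat(sprintf("  outcome:  %s (log-OR)\n", object@outcomeLabel))
  if (nrow(df)) {
    cat(sprintf("  flipped during harmonization: %d\n", sum(df$flipped)))
    show <- utils::head(df[, c("rsid", "beta_x", "se_x", "beta_y", "se_y")], 4)
    print(show, row.names = FALSE, digits = 4)
    if (nrow(df) > 4) cat(sprintf("  ... and %d more\n", nrow(df) - 4))
  }
  invisible(NULL)
})

#' @rdname mrBeta
setMethod("mrBeta", "MREstimate", function(x) x@beta)
#' @rdname mrBeta
setMethod("mrSE", "MREstimate", function(x) x@se)
#' @rdname mrBeta
setMethod("mrPval", "MREstimate", function(x) x@pval)
#' @rdname mrBeta
setMethod("mrCI", "MREstimate", function(x) c(low = x@ciLow, high = x@ciHigh))
#' @rdname mrBeta
setMethod("mrOR", "MREstimate", function(x)
  c(or = exp(x@beta), ci_low = exp(x@ciLow), ci_high = exp(x@ciHigh)))
#' @rdname mrBeta
setMethod("mrMethod", "MREstimate", function(x) x@method)
#' @rdname mrBeta
setMethod("nSnps", "MREstimate", function(x) x@nSnps)
#' @rdname mrBeta
setMethod("mrExtras", "MREstimate", function(x) x@extras)

#' Tidy one-row summary of an MREstimate
#'
#' @param x an [MREstimate-class].
#' @param row.names,optional,... ignored.
#' @return one-row data.frame: method, n_snps, beta, se, or, or_ci_low,
#'   or_ci_high, pval, intercept, intercept_p, notes.
#' @export
as.data.frame.MREstimate <- function(x, row.names = NULL,
                                     optional = FALSE, ...) {
  ex <- x@extras
  data.frame(method = x@method, n_snps = x@nSnps,
             beta = x@beta, se = x@se,
             or = exp(x@beta), or_ci_low = exp(x@ciLow),
             or_ci_high = exp(x@ciHigh), pval = x@pval,
             intercept = ex$intercept %||% NA_real_,
             intercept_p = ex$interceptPval %||% NA_real_,
             notes = ex$note %||% "", stringsAsFactors = FALSE)
}

setMethod("show", "MREstimate", function(object) {
  or <- mrOR(object)
  cat(sprintf("MREstimate [%s], %d SNPs (%s-order weights)\n",
              object@method, object@nSnps, object@seOrder))
  cat(sprintf("  log-OR per SD: %.4f (SE %.4f)\n", object@beta, object@se))
  cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              or["or"], or["ci_low"], or["ci_high"], object@pval))
  if (!is.null(object@extras$intercept))
    cat(sprintf("  Egger intercept: %.4g (SE %.4g), p = %.3g\n",
                object@extras$intercept, object@extras$interceptSE,
                object@extras$interceptPval))
  invisible(NULL)
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("Cochran Q = %.3f on %d df, p = %.3g; I2MR = %.1f%%\n",
              object@q, object@df, object@pval, object@i2MR))
  cat(sprintf("  excessive heterogeneity (I2MR>25%% and p<0.05): %s\n",
              object@flagPleiotropy))
  invisible(NULL)
})

setMethod("show", "EggerModelSelection", function(object) {
  cat(sprintf("Rucker Q' = %.3f on %d df (p = %.3g)\n",
              object@qPrime, object@dfPrime, object@pQPrime))
  cat(sprintf("  Q - Q' = %.3f, chi-square(1) p = %.3g; Egger preferred: %s\n",
              object@qMinusQPrime, object@pModelTest, object@eggerPreferred))
  invisible(NULL)
})

setMethod("show", "IGXResult", function(object) {
  cat(sprintf("I2GX = %.1f%% (Q_GX = %.2f on %d df); low NOME-bias risk (>95%%): %s\n",
              object@i2GX, object@qGX, object@df, object@lowBiasFlag))
  invisible(NULL)
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO (%d simulations)\n", object@nSim))
  cat(sprintf("  global test: RSS = %.4g, p = %.4g\n",
              object@globalRSS, object@globalPval))
  if (length(object@outliers)) {
    cat(sprintf("  outliers (%d): %s\n", length(object@outliers),
                paste(object@outliers, collapse = ", ")))
    cat(sprintf("  distortion test p = %.3g\n", object@distortionPval))
  } else cat("  no outliers detected\n")
  invisible(NULL)
})

setMethod("show", "StudyReport", function(object) {
  cat(sprintf("StudyReport: %d outcome(s)\n", length(object@outcomes)))
  for (nm in names(object@outcomes)) {
    oc <- object@outcomes[[nm]]
    if (!is.null(oc$error)) {
      cat(sprintf("  %s: FAILED (%s)\n", nm, oc$error))
      next
    }
    ok <- vapply(oc$estimates, function(e) methods::is(e, "MREstimate"),
                 logical(1))
    cat(sprintf("  %s [%s tier]: %d/%d methods computed, %d SNPs\n",
                nm, oc$tier, sum(ok), length(ok), length(oc$instrumentSet)))
  }
  invisible(NULL)
})
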