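#' @import methods
NULL

## Required columns of the instrument table carried by an InstrumentSet.
.INSTRUMENT_COLS <- c("rsid", "beta_x", "se_x", "beta_y", "se_y",
                      "eaf_x", "n_x", "aligned_allele", "flipped")

#' InstrumentSet: exposure/outcome-aligned genetic instruments
#'
#' An `InstrumentSet` holds the harmonized per-SNP summary statistics used by
#' every Mendelian randomization estimator in this package: the SNP-exposure
#' effect `beta_x` (SD units of the exposure) with standard error `se_x`, and
#' the SNP-outcome effect `beta_y` (log odds ratio) with standard error
#' `se_y`, all expressed on a common effect allele. It is usually produced by
#' [harmonize()] and consumed by [mrIVW()], [mrEgger()], [mrWeightedMedian()],
#' [mrWeightedMode()], [mrPresso()] and the heterogeneity diagnostics.
#'
#' @slot instruments data.frame with columns `rsid`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y`, `eaf_x`, `n_x`, `aligned_allele`, `flipped`.
#' @slot exposureLabel single string naming the exposure trait.
#' @slot outcomeLabel single string naming the outcome trait.
#' @slot provenance list recording input files, harmonization dispositions,
#'   applied exclusions and other audit information.
#'
#' @seealso [InstrumentSet()] for the constructor, [instruments()],
#'   [applyExclusions()], [writeInstrumentTable()].
#' @export
setClass("InstrumentSet",
         representation(instruments = "data.frame",
                        exposureLabel = "character",
                        outcomeLabel = "character",
                        provenance = "list"))

setValidity("InstrumentSet", function(object) {
  df <- object@instruments
  msgs <- character()
  missing <- setdiff(.INSTRUMENT_COLS, names(df))
  if (length(missing))
    return(paste("instrument table lacks columns:",
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(df$rsid))
    msgs <- c(msgs, "rsids must be unique")
  if (nrow(df)) {
    if (!all(is.finite(df$beta_x)) || !all(is.finite(df$beta_y)))
      msgs <- c(msgs, "beta_x and beta_y must be finite")
    if (!all(is.finite(df$se_x) & df$se_x > 0))
      msgs <- c(msgs, "se_x must be positive and finite")
    if (!all(is.finite(df$se_y) & df$se_y > 0))
      msgs <- c(msgs, "se_y must be positive and finite")
    if (!is.logical(df$flipped))
      msgs <- c(msgs, "flipped must be logical")
  }
  if (length(object@exposureLabel) != 1L || length(object@outcomeLabel) != 1L)
    msgs <- c(msgs, "exposureLabel and outcomeLabel must be single strings")
  if (length(msgs)) msgs else TRUE
})

#' Construct an InstrumentSet
#'
#' Low-level constructor used by [harmonize()] and the test/simulation
#' helpers. Most users obtain an `InstrumentSet` from [harmonize()].
#'
#' @param rsid character vector of SNP identifiers (unique).
#' @param betaX,seX SNP-exposure effects (SD units) and standard errors.
#' @param betaY,seY SNP-outcome effects (log-OR) and standard errors.
#' @param eafX effect-allele frequency of the aligned allele in the exposure
#'   study (`NA` when unknown); used only for F statistics.
#' @param nX exposure GWAS sample size per SNP (`NA` when unknown).
#' @param alignedAllele the common effect allele after harmonization.
#' @param flipped logical audit flag: was the outcome effect sign-flipped?
#' @param exposureLabel,outcomeLabel trait names carried through reports.
#' @param provenance free-form audit list.
#' @return a validated [InstrumentSet-class] object.
#' @examples
#' x <- InstrumentSet(rsid = c("rs1", "rs2", "rs3"),
#'                    betaX = c(0.1, 0.12, 0.08), seX = rep(0.01, 3),
#'                    betaY = c(0.05, 0.07, 0.04), seY = rep(0.02, 3))
#' mrIVW(x)
#' @export
InstrumentSet <- function(rsid, betaX, seX, betaY, seY,
                          eafX = NA_real_, nX = NA_real_,
                          alignedAllele = NA_character_, flipped = FALSE,
                          exposureLabel = "exposure",
                          outcomeLabel = "outcome",
                          provenance = list()) {
  n <- length(rsid)
  df <- data.frame(rsid = as.character(rsid),
                   beta_x = as.numeric(betaX),
                   se_x = as.numeric(seX),
                   beta_y = as.numeric(betaY),
                   se_y = as.numeric(seY),
                   eaf_x = rep_len(as.numeric(eafX), n),
                   n_x = rep_len(as.numeric(nX), n),
                   aligned_allele = rep_len(as.character(alignedAllele), n),
                   flipped = rep_len(as.logical(flipped), n),
                   stringsAsFactors = FALSE)
  new("InstrumentSet", instruments = df,
      exposureLabel = exposureLabel, outcomeLabel = outcomeLabel,
      provenance = provenance)
}

#' MREstimate: a pooled Mendelian randomization estimate
#'
#' One method's pooled causal estimate: the log odds ratio of the outcome per
#' SD-unit increase in the exposure, its standard error, 95% confidence
#' interval and p-value, together with method-specific extras (for MR-Egger
#' the intercept and its test; for bootstrap estimators the replicate count
#' and seed).
#'
#' @slot method method tag, one of `ivw_fixed`, `ivw_excl_pleiotropy`,
#'   `egger`, `presso_raw`, `presso_outlier_corrected`, `weighted_median`,
#'   `weighted_mode`.
#' @slot beta,se pooled log-OR per SD and its standard error.
#' @slot ciLow,ciHigh 95% confidence bounds on the log-OR scale.
#' @slot pval two-sided p-value.
#' @slot nSnps number of SNPs contributing.
#' @slot seOrder delta-method order used for per-SNP weights
#'   (`"second"` or `"first"`).
#' @slot extras method-specific named list.
#' @seealso [mrBeta()], [mrOR()], accessors; `as.data.frame` gives a tidy row.
#' @export
setClass("MREstimate",
         representation(method = "character", beta = "numeric",
                        se = "numeric", ciLow = "numeric", ciHigh = "numeric",
                        pval = "numeric", nSnps = "integer",
                        seOrder = "character", extras = "list"))

setValidity("MREstimate", function(object) {
  msgs <- character()
  if (length(object@beta) != 1L || !is.finite(object@beta))
    msgs <- c(msgs, "beta must be a single finite number")
  if (!is.finite(object@se) || object@se < 0)
    msgs <- c(msgs, "se must be non-negative and finite")
  if (object@ciLow > object@beta + 1e-12 || object@ciHigh < object@beta - 1e-12)
    msgs <- c(msgs, "confidence interval must bracket the estimate")
  if (object@pval < 0 || object@pval > 1)
    msgs <- c(msgs, "pval must lie in [0, 1]")
  if (object@nSnps < 1L)
    msgs <- c(msgs, "nSnps must be >= 1")
  if (length(msgs)) msgs else TRUE
})

setClassUnion("MREstimateOrNULL", c("MREstimate", "NULL"))

#' HeterogeneityResult: Cochran Q heterogeneity of per-SNP MR estimates
#'
#' Output of [cochranQ()]. Excessive heterogeneity between per-SNP Wald
#' ratios is read as evidence of pleiotropy: the flag fires when I2MR exceeds
#' 25% and the Q-derived p-value falls below 0.05.
#'
#' @slot q Cochran Q statistic.
#' @slot df degrees of freedom (J - 1).
#' @slot pval upper-tail chi-square p-value.
#' @slot i2MR I2 heterogeneity percentage in [0, 100].
#' @slot flagPleiotropy TRUE when i2MR > 25 and pval < 0.05.
#' @export
setClass("HeterogeneityResult",
         representation(q = "numeric", df = "numeric", pval = "numeric",
                        i2MR = "numeric", flagPleiotropy = "logical"))

#' EggerModelSelection: Rucker Q' and the Egger-vs-IVW model test
#'
#' Output of [ruckerModelSelection()]. Q' is the weighted residual sum of
#' squares of the MR-Egger fit; Q - Q' referred to a 1-df chi-square tests
#' whether freeing the intercept improves fit enough to prefer MR-Egger over
#' fixed-effect IVW.
#'
#' @slot q Cochran Q at the IVW estimate (same weights as the Egger fit).
#' @slot qPrime Rucker Q' (Egger residual heterogeneity).
#' @slot dfPrime J - 2.
#' @slot pQPrime upper-tail chi-square p for Q'.
#' @slot qMinusQPrime the model-selection statistic.
#' @slot pModelTest chi-square(1) p for Q - Q'.
#' @slot eggerPreferred TRUE when pModelTest < 0.05.
#' @export
setClass("EggerModelSelection",
         representation(q = "numeric", qPrime = "numeric", dfPrime = "numeric",
                        pQPrime = "numeric", qMinusQPrime = "numeric",
                        pModelTest = "numeric", eggerPreferred = "logical"))

#' IGXResult: instrument-strength heterogeneity (NOME violation gauge)
#'
#' Output of [i2GX()]. I2GX quantifies heterogeneity between SNP-exposure
#' estimates relative to their measurement error; values above 95% indicate
#' low risk of regression-dilution bias in MR-Egger.
#'
#' @slot qGX heterogeneity statistic of the (oriented) SNP-exposure effects.
#' @slot df J - 1.
#' @slot i2GX percentage in [0, 100].
#' @slot lowBiasFlag TRUE when i2GX > 95.
#' @export
setClass("IGXResult",
         representation(qGX = "numeric", df = "numeric", i2GX = "numeric",
                        lowBiasFlag = "logical"))

#' PressoResult: MR-PRESSO global, outlier and distortion tests
#'
#' Output of [mrPresso()]. Holds the observed residual sum of squares, its
#' simulation-based global p-value, per-SNP Bonferroni-adjusted outlier
#' p-values, the identified outliers, the raw and outlier-corrected IVW
#' estimates, and the distortion test p-value (NA when no outliers were
#' found, in which case `estimateCorrected` is NULL).
#'
#' @slot globalRSS observed residual sum of squares.
#' @slot globalPval empirical global test p-value (add-one rule).
#' @slot outlierPvals named per-SNP Bonferroni-adjusted p-values.
#' @slot outliers rsids flagged at the outlier threshold.
#' @slot estimateRaw IVW estimate on all instruments (tag `presso_raw`).
#' @slot estimateCorrected IVW after removing outliers, or NULL.
#' @slot distortionPval two-sided empirical distortion p (NA if no outliers).
#' @slot nSim number of simulation replicates.
#' @slot settings list with seed, outlier alpha and SE order.
#' @export
setClass("PressoResult",
         representation(globalRSS = "numeric", globalPval = "numeric",
                        outlierPvals = "numeric", outliers = "character",
                        estimateRaw = "MREstimate",
                        estimateCorrected = "MREstimateOrNULL",
                        distortionPval = "numeric", nSim = "integer",
                        settings = "list"))

setValidity("PressoResult", function(object) {
  msgs <- character()
  lo <- 1 / (object@nSim + 1)
  if (object@globalPval < lo - 1e-12 || object@globalPval > 1)
    msgs <- c(msgs, "globalPval must lie in [1/(nSim+1), 1]")
  if (!all(object@outliers %in% names(object@outlierPvals)))
    msgs <- c(msgs, "outliers must be a subset of tested rsids")
  if (length(object@outliers) > 0 && is.null(object@estimateCorrected))
    msgs <- c(msgs, "estimateCorrected must be present when outliers exist")
  if (length(object@outliers) == 0 && !is.null(object@estimateCorrected))
    msgs <- c(msgs, "estimateCorrected must be absent when no outliers")
  if (length(msgs)) msgs else TRUE
})

#' StudyReport: full multi-outcome Mendelian randomization study results
#'
#' Produced by [runStudy()]. One entry per outcome with every requested
#' estimator (or an explicit skip reason), the pleiotropy diagnostics,
#' instrument-strength summaries and tiered significance calls, plus run
#' metadata (seeds, package version, configuration).
#'
#' @slot outcomes named list, one element per outcome label.
#' @slot config the [studyConfig()] list that produced the report.
#' @slot metadata list with package version, master seed and derived seeds.
#' @seealso [renderForestTable()], [writeStudyReport()].
#' @export
setClass("StudyReport",
         representation(outcomes = "list", config = "list",
                        metadata = "list"))
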