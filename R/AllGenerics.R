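#' @include AllClasses.R
NULL

#' Extract the instrument table
#'
#' @param x an [InstrumentSet-class].
#' @return the underlying data.frame of harmonized per-SNP statistics.
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))

#' @rdname instruments
#' @export
setGeneric("exposureLabel", function(x) standardGeneric("exposureLabel"))

#' @rdname instruments
#' @export
setGeneric("outcomeLabel", function(x) standardGeneric("outcomeLabel"))

#' @rdname instruments
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Per-SNP Wald ratio estimates
#'
#' @param x an [InstrumentSet-class].
#' @param seOrder `"second"` (default, delta method acknowledging uncertainty
#'   in the SNP-exposure estimate) or `"first"`.
#' @return data.frame with columns `rsid`, `theta` (Wald ratio, log-OR per
#'   SD), `se` (delta-method standard error) and `weight` (`se^-2`).
#' @export
setGeneric("waldRatios",
           function(x, seOrder = c("second", "first"))
             standardGeneric("waldRatios"))

#' Fixed-effect inverse-variance weighted MR estimate
#'
#' @param x an [InstrumentSet-class] or a Wald-ratio data.frame as returned
#'   by [waldRatios()].
#' @param ... passed between methods; `seOrder`, `method` tag override.
#' @return an [MREstimate-class].
#' @export
setGeneric("mrIVW", function(x, ...) standardGeneric("mrIVW"))

#' MR-Egger regression
#'
#' @param x an [InstrumentSet-class] (at least 3 instruments).
#' @param ... `seOrder`.
#' @return an [MREstimate-class] whose `extras` carry the intercept, its SE
#'   and p-value, Rucker Q' and the overdispersion factor.
#' @export
setGeneric("mrEgger", function(x, ...) standardGeneric("mrEgger"))

#' Weighted median MR estimate
#'
#' @param x an [InstrumentSet-class] or Wald-ratio data.frame.
#' @param ... `nBoot`, `seed`, `seOrder`.
#' @return an [MREstimate-class].
#' @export
setGeneric("mrWeightedMedian",
           function(x, ...) standardGeneric("mrWeightedMedian"))

#' Weighted mode-based MR estimate
#'
#' @param x an [InstrumentSet-class] or Wald-ratio data.frame.
#' @param ... `phi`, `nBoot`, `seed`, `seOrder`.
#' @return an [MREstimate-class].
#' @export
setGeneric("mrWeightedMode",
           function(x, ...) standardGeneric("mrWeightedMode"))

#' Cochran Q heterogeneity of per-SNP MR estimates
#'
#' @param x an [InstrumentSet-class] or Wald-ratio data.frame (>= 2 SNPs).
#' @param ... `pooledBeta` (defaults to the fixed-effect IVW estimate),
#'   `seOrder`.
#' @return a [HeterogeneityResult-class].
#' @export
setGeneric("cochranQ", function(x, ...) standardGeneric("cochranQ"))

#' Rucker model selection between IVW and MR-Egger
#'
#' @param x an [InstrumentSet-class] (>= 3 instruments).
#' @param ... `seOrder`.
#' @return an [EggerModelSelection-class].
#' @export
setGeneric("ruckerModelSelection",
           function(x, ...) standardGeneric("ruckerModelSelection"))

#' Instrument-strength heterogeneity I2GX
#'
#' @param x an [InstrumentSet-class] (>= 2 instruments).
#' @return an [IGXResult-class].
#' @export
setGeneric("i2GX", function(x) standardGeneric("i2GX"))

#' MR-PRESSO global, outlier and distortion tests
#'
#' @param x an [InstrumentSet-class] (>= 4 instruments).
#' @param ... `nSim`, `seed`, `outlierAlpha`, `seOrder`.
#' @return a [PressoResult-class].
#' @export
setGeneric("mrPresso", function(x, ...) standardGeneric("mrPresso"))

#' Remove listed SNPs from an instrument set
#'
#' @param x an [InstrumentSet-class].
#' @param rsids character vector of rsIDs to exclude; unknown rsIDs are
#'   ignored with a note in the provenance.
#' @return a new [InstrumentSet-class]; the input is not modified.
#' @export
setGeneric("applyExclusions",
           function(x, rsids) standardGeneric("applyExclusions"))

#' Per-SNP instrument strength (R2 and F statistic)
#'
#' @param x an [InstrumentSet-class] whose instrument table carries the
#'   exposure effect-allele frequency and sample size.
#' @return data.frame with `rsid`, `r2`, `n`, `f_stat` and `weak` (TRUE when
#'   F <= 10).
#' @export
setGeneric("instrumentStrength",
           function(x) standardGeneric("instrumentStrength"))

#' Funnel plot data
#'
#' @param x an [InstrumentSet-class] or Wald-ratio data.frame.
#' @param ... `pooledBeta` (defaults to the IVW estimate), `seOrder`.
#' @return data.frame with one row per SNP: `rsid`, `theta`, `precision`
#'   (1/se) and the pooled reference `pooled` (recycled so the table
#'   round-trips through TSV).
#' @export
setGeneric("funnelData", function(x, ...) standardGeneric("funnelData"))

#' Radial plot data
#'
#' @param x an [InstrumentSet-class] or Wald-ratio data.frame.
#' @param ... `seOrder`.
#' @return data.frame with one row per SNP: `rsid`, `sqrt_w`,
#'   `theta_sqrt_w` and the IVW reference `slope` (recycled).
#' @export
setGeneric("radialData", function(x, ...) standardGeneric("radialData"))

#' Accessors for MREstimate
#'
#' @param x an [MREstimate-class].
#' @return `mrBeta`, `mrSE`, `mrPval`: single numbers on the log-OR scale;
#'   `mrCI`: length-2 vector (low, high); `mrOR`: named vector `or`,
#'   `ci_low`, `ci_high` on the odds-ratio scale; `mrMethod`: the method tag;
#'   `nSnps`: integer; `mrExtras`: named list.
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))
#' @rdname mrBeta
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))
#' @rdname mrBeta
#' @export
setGeneric("mrPval", function(x) standardGeneric("mrPval"))
#' @rdname mrBeta
#' @export
setGeneric("mrCI", function(x) standardGeneric("mrCI"))
#' @rdname mrBeta
#' @export
setGeneric("mrOR", function(x) standardGeneric("mrOR"))
#' @rdname mrBeta
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))
#' @rdname mrBeta
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname mrBeta
#' @export
setGeneric("mrExtras", function(x) standardGeneric("mrExtras"))
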