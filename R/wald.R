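#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Instrument F statistic
#'
#' Strength of a genetic instrument from the proportion of exposure variance
#' it explains: `F = r2 * (n - 2) / (1 - r2)`. An F statistic above 10 is
#' conventionally read as low risk of weak-instrument bias.
#'
#' @param r2 variance explained, in `[0, 1)` (vectorized).
#' @param n GWAS sample size, `> 2` (vectorized).
#' @return numeric vector of F values.
#' @examples
#' fStatistic(0.5, 4)            # 2
#' fStatistic(0.001, 166066)     # ~166.2
#' @export
fStatistic <- function(r2, n) {
  if (any(!is.finite(r2) | r2 < 0 | r2 >= 1))
    stop("r2 must lie in [0, 1)")
  if (any(!is.finite(n) | n <= 2))
    stop("n must be > 2")
  r2 * (n - 2) / (1 - r2)
}

#' @describeIn instrumentStrength per-SNP strength from the instrument
#'   table's exposure allele frequency and sample size. R2 is approximated on
#'   the standardized-exposure scale as `2 * eaf * (1 - eaf) * beta_x^2`.
setMethod("instrumentStrength", "InstrumentSet", function(x) {
  df <- x@instruments
  if (!nrow(df)) stop("empty instrument set")
  if (anyNA(df$eaf_x) || anyNA(df$n_x))
    stop("instrument table lacks eaf/sample size; cannot compute F statistics")
  r2 <- pmin(2 * df$eaf_x * (1 - df$eaf_x) * df$beta_x^2, 1 - 1e-12)
  f <- fStatistic(r2, df$n_x)
  data.frame(rsid = df$rsid, r2 = r2, n = df$n_x, f_stat = f,
             weak = f <= 10, stringsAsFactors = FALSE)
})

## Core per-SNP ratio computation shared by the estimators.
.waldRatiosCore <- function(rsid, bx, sx, by, sy, seOrder) {
  zero <- bx == 0
  if (any(zero))
    stop("Wald ratio undefined (beta_x = 0) for: ",
         paste(rsid[zero], collapse = ", "))
  theta <- by / bx
  se <- if (seOrder == "first") {
    sy / abs(bx)
  } else {
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  }
  data.frame(rsid = rsid, theta = theta, se = se, weight = se^-2,
             stringsAsFactors = FALSE)
}

#' @describeIn waldRatios per-SNP ratio table from a harmonized set. The
#'   second-order delta-method SE `sqrt(seY^2/bX^2 + bY^2 seX^2/bX^4)`
#'   acknowledges uncertainty in the SNP-exposure estimate and is the
#'   default; `"first"` gives `seY/|bX|`.
setMethod("waldRatios", "InstrumentSet",
          function(x, seOrder = c("second", "first")) {
  seOrder <- .matchSeOrder(seOrder)
  df <- x@instruments
  if (!nrow(df)) stop("empty instrument set")
  .waldRatiosCore(df$rsid, df$beta_x, df$se_x, df$beta_y, df$se_y, seOrder)
})
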