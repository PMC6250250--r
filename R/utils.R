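`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a temporary RNG state seeded with `seed`;
## the caller's RNG stream is restored afterwards. seed = NULL uses the
## current stream (and does not restore it).
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

.normPval <- function(beta, se) {
  z <- ifelse(se > 0, abs(beta / se), Inf)
  2 * stats::pnorm(-z)
}

## Internal MREstimate factory. df = NULL -> normal reference; otherwise a
## t reference with the given degrees of freedom (MR-Egger convention).
.newMREstimate <- function(method, beta, se, nSnps, seOrder,
                           extras = list(), df = NULL) {
  if (is.null(df)) {
    crit <- stats::qnorm(0.975)
    pval <- .normPval(beta, se)
  } else {
    crit <- stats::qt(0.975, df)
    pval <- 2 * stats::pt(-abs(beta / se), df)
  }
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = beta - crit * se, ciHigh = beta + crit * se,
      pval = pval, nSnps = as.integer(nSnps), seOrder = seOrder,
      extras = extras)
}

.matchSeOrder <- function(seOrder) match.arg(seOrder, c("second", "first"))

## Validate a Wald-ratio table (as produced by waldRatios); fills in the
## weight column when absent.
.checkRatios <- function(ratios, minSnps = 1L, caller = "estimator") {
  if (!is.data.frame(ratios) || !all(c("theta", "se") %in% names(ratios)))
    stop(caller, " requires a data.frame with columns 'theta' and 'se'",
         call. = FALSE)
  if (is.null(ratios$weight)) ratios$weight <- ratios$se^-2
  if (is.null(ratios$rsid)) ratios$rsid <- paste0("snp", seq_len(nrow(ratios)))
  if (nrow(ratios) < minSnps)
    stop(caller, " requires at least ", minSnps, " SNPs, got ", nrow(ratios),
         call. = FALSE)
  if (any(!is.finite(ratios$se) | ratios$se <= 0))
    stop(caller, ": all ratio standard errors must be positive", call. = FALSE)
  ratios
}
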