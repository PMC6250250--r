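#' @include AllClasses.R AllGenerics.R utils.R summary-io.R estimators.R
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic two-sample GWAS generator. The defaults mirror
#' the platelet-count study design: 219 instruments discovered in an exposure
#' GWAS of 166,066 subjects (exposure in SD units), an outcome GWAS of 60,341
#' cases and 454,450 controls (log-OR scale), and a genome-wide significance
#' cutoff of 5e-8. `h2Instruments` (total exposure variance explained by the
#' panel, default 0.15) is chosen so realized per-SNP F statistics span
#' roughly 30-2000, matching the published envelope of the panel.
#'
#' @param jSnps number of candidate instruments.
#' @param nExposure exposure GWAS sample size.
#' @param nCases,nControls outcome GWAS sizes (binary trait).
#' @param thetaTrue true causal effect, log-OR per SD of exposure.
#' @param h2Instruments total variance explained by the candidate panel.
#' @param mafRange minor-allele-frequency interval within (0, 0.5].
#' @param pleiotropyFrac fraction pi of SNPs with a direct (pleiotropic)
#'   outcome effect.
#' @param pleiotropyMean,pleiotropySD mean and SD of the pleiotropic effects
#'   alpha_j (log-OR units); mean 0 gives balanced, nonzero directional
#'   pleiotropy.
#' @param insideViolation if TRUE, the pleiotropic mean scales with the SNP's
#'   instrument strength (violating the InSIDE assumption).
#' @param nOutliers number of planted outlier SNPs.
#' @param outlierOffset pleiotropic offset added to each outlier, expressed
#'   as a multiple of that SNP's outcome standard error.
#' @param gwThreshold instrument-selection p-value cutoff, applied in an
#'   independent discovery replicate to avoid winner's curse; `NULL` disables
#'   selection and retains all `jSnps`.
#' @param scrambleAlleles if TRUE, the outcome table's allele coding is
#'   randomly swapped/strand-flipped (meaning preserved) to exercise
#'   harmonization.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(jSnps = 219L, nExposure = 166066L, nCases = 60341L,
                      nControls = 454450L, thetaTrue = 0.07,
                      h2Instruments = 0.15, mafRange = c(0.01, 0.5),
                      pleiotropyFrac = 0, pleiotropyMean = 0,
                      pleiotropySD = 0, insideViolation = FALSE,
                      nOutliers = 0L, outlierOffset = 0,
                      gwThreshold = 5e-8, scrambleAlleles = FALSE,
                      seed = NULL) {
  cfg <- list(jSnps = as.integer(jSnps), nExposure = as.integer(nExposure),
              nCases = as.integer(nCases), nControls = as.integer(nControls),
              thetaTrue = thetaTrue, h2Instruments = h2Instruments,
              mafRange = mafRange, pleiotropyFrac = pleiotropyFrac,
              pleiotropyMean = pleiotropyMean, pleiotropySD = pleiotropySD,
              insideViolation = isTRUE(insideViolation),
              nOutliers = as.integer(nOutliers),
              outlierOffset = outlierOffset,
              gwThreshold = gwThreshold,
              scrambleAlleles = isTRUE(scrambleAlleles), seed = seed)
  stopifnot(cfg$jSnps > 0, cfg$nExposure > 2, cfg$nCases > 0,
            cfg$nControls > 0, cfg$h2Instruments > 0, cfg$h2Instruments < 1,
            length(cfg$mafRange) == 2, cfg$mafRange[1] > 0,
            cfg$mafRange[2] <= 0.5, cfg$mafRange[1] <= cfg$mafRange[2],
            cfg$pleiotropyFrac >= 0, cfg$pleiotropyFrac <= 1,
            cfg$pleiotropySD >= 0, cfg$nOutliers >= 0,
            cfg$nOutliers <= cfg$jSnps,
            is.null(cfg$gwThreshold) ||
              (cfg$gwThreshold > 0 && cfg$gwThreshold < 1))
  class(cfg) <- c("SimConfig", "list")
  cfg
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generates exposure and outcome association tables in the same dialect
#' [readAssociationTable()] reads, together with the generating truth for
#' recovery tests. Per SNP j: the minor allele frequency is uniform on
#' `mafRange`; true effects `b_j` are half-normal (effect allele oriented to
#' increase the exposure) and rescaled so the panel explains exactly
#' `h2Instruments` of exposure variance; standard errors follow the standard
#' large-sample approximations `seX = 1/sqrt(2 maf (1-maf) nExposure)` and
#' `seY = sqrt((1/nCases + 1/nControls) / (2 maf (1-maf)))`; observed effects
#' are drawn around `b_j` (exposure) and `thetaTrue * b_j + alpha_j`
#' (outcome), where `alpha_j` is the pleiotropic effect (zero with
#' probability `1 - pleiotropyFrac`). Planted outliers receive an extra
#' offset of `outlierOffset` outcome standard errors. When `gwThreshold` is
#' set, instruments are retained only if an independent discovery replicate
#' of the exposure effect reaches that significance, mirroring a two-sample
#' design free of winner's curse.
#'
#' @param config a [simConfig()] object.
#' @return list with elements `exposure` and `outcome` (standardized
#'   association data.frames) and `truth` (class `SimTruth`: `thetaTrue`,
#'   per-SNP `b` and `alpha`, `outlierRsids`, `keptRsids`, realized `meanF`,
#'   and the config).
#' @examples
#' sim <- simulateTwoSample(simConfig(jSnps = 60, seed = 1))
#' x <- harmonize(sim$exposure, sim$outcome)
#' mrIVW(x)
#' @export
simulateTwoSample <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  withSeed(config$seed, .simulateTwoSampleImpl(config))
}

.simulateTwoSampleImpl <- function(cfg) {
  J <- cfg$jSnps
  rsid <- sprintf("rs%07d", seq_len(J))
  maf <- stats::runif(J, cfg$mafRange[1], cfg$mafRange[2])
  varG <- 2 * maf * (1 - maf)  # variance of the standardized-exposure genotype

  bRaw <- abs(stats::rnorm(J))
  b <- bRaw * sqrt(cfg$h2Instruments / sum(varG * bRaw^2))

  seX <- 1 / sqrt(varG * cfg$nExposure)
  bXobs <- stats::rnorm(J, b, seX)
  seY <- sqrt((1 / cfg$nCases + 1 / cfg$nControls) / varG)

  ## instrument selection on an independent discovery replicate
  keep <- rep(TRUE, J)
  if (!is.null(cfg$gwThreshold)) {
    bXdisc <- stats::rnorm(J, b, seX)
    pDisc <- 2 * stats::pnorm(-abs(bXdisc / seX))
    keep <- pDisc < cfg$gwThreshold
    if (!any(keep))
      stop("no instruments pass the selection threshold; ",
           "increase h2Instruments or jSnps")
  }

  alpha <- numeric(J)
  if (cfg$pleiotropyFrac > 0) {
    invalid <- stats::runif(J) < cfg$pleiotropyFrac
    mu <- if (cfg$insideViolation) {
      cfg$pleiotropyMean * abs(b) / mean(abs(b))
    } else rep(cfg$pleiotropyMean, J)
    alpha[invalid] <- stats::rnorm(sum(invalid), mu[invalid],
                                   cfg$pleiotropySD)
  }
  outlierRsids <- character(0)
  if (cfg$nOutliers > 0) {
    pool <- which(keep)
    oIdx <- pool[sample.int(length(pool), min(cfg$nOutliers, length(pool)))]
    alpha[oIdx] <- alpha[oIdx] + cfg$outlierOffset * seY[oIdx]
    outlierRsids <- rsid[oIdx]
  }

  bYobs <- stats::rnorm(J, cfg$thetaTrue * b + alpha, seY)

  ## p-values floored at the smallest positive double so tables always pass
  ## the (0, 1] validation
  pv <- function(z) pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  exposure <- data.frame(rsid = rsid, effect_allele = "A", other_allele = "G",
                         eaf = maf, beta = bXobs, se = seX,
                         pval = pv(bXobs / seX), n = cfg$nExposure,
                         stringsAsFactors = FALSE)
  outcome <- data.frame(rsid = rsid, effect_allele = "A", other_allele = "G",
                        eaf = maf, beta = bYobs, se = seY,
                        pval = pv(bYobs / seY),
                        n = cfg$nCases + cfg$nControls,
                        stringsAsFactors = FALSE)
  if (cfg$scrambleAlleles) {
    swap <- stats::runif(J) < 0.5
    outcome$effect_allele[swap] <- "G"
    outcome$other_allele[swap] <- "A"
    outcome$beta[swap] <- -outcome$beta[swap]
    outcome$eaf[swap] <- 1 - outcome$eaf[swap]
    strand <- stats::runif(J) < 0.5  # A/G <-> T/C, non-palindromic
    outcome$effect_allele[strand] <- .COMPLEMENT[outcome$effect_allele[strand]]
    outcome$other_allele[strand] <- .COMPLEMENT[outcome$other_allele[strand]]
  }

  exposure <- exposure[keep, , drop = FALSE]
  outcome <- outcome[keep, , drop = FALSE]
  rownames(exposure) <- rownames(outcome) <- NULL
  attr(exposure, "traitScale") <- "sd"
  attr(exposure, "label") <- "simulated_exposure"
  attr(outcome, "traitScale") <- "log_or"
  attr(outcome, "label") <- "simulated_outcome"

  truth <- list(thetaTrue = cfg$thetaTrue, rsid = rsid, b = b, alpha = alpha,
                outlierRsids = outlierRsids, keptRsids = rsid[keep],
                meanF = mean((bXobs[keep] / seX[keep])^2), config = cfg)
  class(truth) <- c("SimTruth", "list")
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Parameter-recovery study over a grid of simulation scenarios
#'
#' For each scenario (row of `grid`, columns overriding [simConfig()]
#' defaults) and each requested method, simulates `nReps` panels, estimates
#' the causal effect, and summarizes mean bias, RMSE, empirical 95% CI
#' coverage and the rejection rate at p < 0.05 (type-I error when
#' `thetaTrue = 0`, power otherwise). For MR-Egger the intercept-test
#' rejection rate is also reported.
#'
#' @param grid data.frame of scenario overrides; `NULL` gives a default
#'   three-scenario grid (no pleiotropy; balanced; directional).
#' @param nReps simulated panels per scenario.
#' @param seed master seed; per-panel seeds are derived from it.
#' @param methods subset of `c("ivw", "egger", "weighted_median",
#'   "weighted_mode")`.
#' @param nBoot bootstrap replicates for the median/mode estimators.
#' @return data.frame with one row per scenario x method.
#' @export
parameterRecoverySuite <- function(grid = NULL, nReps = 100, seed = 1,
                                   methods = c("ivw", "egger",
                                               "weighted_median"),
                                   nBoot = 200) {
  methods <- match.arg(methods,
                       c("ivw", "egger", "weighted_median", "weighted_mode"),
                       several.ok = TRUE)
  if (is.null(grid))
    grid <- data.frame(
      scenario = c("no_pleiotropy", "balanced", "directional"),
      pleiotropyFrac = c(0, 0.3, 0.3),
      pleiotropyMean = c(0, 0, 0.02),
      pleiotropySD = c(0, 0.02, 0.02),
      stringsAsFactors = FALSE)
  scenarioNames <- if ("scenario" %in% names(grid)) grid$scenario
                   else paste0("scenario", seq_len(nrow(grid)))
  overrideCols <- setdiff(names(grid), "scenario")
  seeds <- withSeed(seed,
    matrix(sample.int(.Machine$integer.max - 1, nrow(grid) * nReps),
           nrow(grid), nReps))

  rows <- list()
  for (g in seq_len(nrow(grid))) {
    args <- as.list(grid[g, overrideCols, drop = FALSE])
    args <- args[!vapply(args, is.na, logical(1))]
    est <- array(NA_real_, c(nReps, length(methods), 4),
                 dimnames = list(NULL, methods,
                                 c("beta", "ciLow", "ciHigh", "pval")))
    interceptP <- rep(NA_real_, nReps)
    thetaTrue <- NA_real_
    for (r in seq_len(nReps)) {
      cfg <- do.call(simConfig, c(args, list(seed = seeds[g, r])))
      thetaTrue <- cfg$thetaTrue
      sim <- simulateTwoSample(cfg)
      x <- harmonize(sim$exposure, sim$outcome)
      for (m in methods) {
        fit <- switch(m,
          ivw = mrIVW(x),
          egger = mrEgger(x),
          weighted_median = mrWeightedMedian(x, nBoot = nBoot,
                                             seed = seeds[g, r]),
          weighted_mode = mrWeightedMode(x, nBoot = nBoot,
                                         seed = seeds[g, r]))
        est[r, m, ] <- c(mrBeta(fit), mrCI(fit), mrPval(fit))
        if (m == "egger") interceptP[r] <- mrExtras(fit)$interceptPval
      }
    }
    for (m in methods) {
      bias <- est[, m, "beta"] - thetaTrue
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scenarioNames[g], method = m, n_reps = nReps,
        theta_true = thetaTrue,
        mean_bias = mean(bias), rmse = sqrt(mean(bias^2)),
        coverage = mean(est[, m, "ciLow"] <= thetaTrue &
                          thetaTrue <= est[, m, "ciHigh"]),
        rejection_rate = mean(est[, m, "pval"] < 0.05),
        intercept_rejection_rate =
          if (m == "egger") mean(interceptP < 0.05) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
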