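#' @include AllClasses.R AllGenerics.R utils.R summary-io.R estimators.R heterogeneity.R presso.R
NULL

.METHOD_ORDER <- c("ivw_fixed", "ivw_excl_pleiotropy", "egger", "presso_raw",
                   "presso_outlier_corrected", "weighted_median",
                   "weighted_mode")

#' Study configuration
#'
#' Declarative description of a full multi-outcome Mendelian randomization
#' study: one exposure table, one or more outcome tables with a significance
#' tier each, an optional pleiotropic-SNP exclusion list, the method battery
#' and its settings. Primary outcomes are tested at `alphaPrimary` (default
#' 0.025, a Bonferroni correction of 0.05 across two primary outcomes);
#' secondary outcomes at `alphaSecondary` (default 0.05).
#'
#' @param exposureFile path to the exposure association table (SD units).
#' @param outcomes list of entries `list(label=, file=, tier=)` with tier
#'   `"primary"` or `"secondary"`, or a data.frame with those columns.
#' @param exclusionFile optional path to a plain-text rsID exclusion list
#'   (one per line, `#` comments) used for the sensitivity IVW.
#' @param methods method tags to run, a subset of the canonical seven
#'   (`ivw_fixed`, `ivw_excl_pleiotropy`, `egger`, `presso_raw`,
#'   `presso_outlier_corrected`, `weighted_median`, `weighted_mode`).
#' @param seOrder delta-method order for all per-SNP weights.
#' @param nBoot bootstrap replicates for median/mode estimators.
#' @param pressoNSim MR-PRESSO simulation replicates.
#' @param seed master seed; per-outcome method seeds are derived from it.
#' @param alphaPrimary,alphaSecondary tier significance thresholds.
#' @param palindromePolicy passed to [harmonize()].
#' @param columnMap optional column mapping passed to
#'   [readAssociationTable()].
#' @return a validated list of class `StudyConfig`.
#' @export
studyConfig <- function(exposureFile, outcomes, exclusionFile = NULL,
                        methods = .METHOD_ORDER,
                        seOrder = c("second", "first"), nBoot = 1000,
                        pressoNSim = 1000, seed = 1,
                        alphaPrimary = 0.025, alphaSecondary = 0.05,
                        palindromePolicy = "infer_by_eaf",
                        columnMap = NULL) {
  seOrder <- .matchSeOrder(seOrder)
  if (is.data.frame(outcomes))
    outcomes <- lapply(seq_len(nrow(outcomes)), function(i)
      as.list(outcomes[i, c("label", "file", "tier")]))
  if (!length(outcomes)) stop("at least one outcome is required")
  for (oc in outcomes) {
    if (!all(c("label", "file", "tier") %in% names(oc)))
      stop("each outcome needs label, file and tier")
    if (!oc$tier %in% c("primary", "secondary"))
      stop("outcome tier must be 'primary' or 'secondary'")
  }
  methods <- match.arg(methods, .METHOD_ORDER, several.ok = TRUE)
  stopifnot(alphaPrimary > 0, alphaPrimary < 1,
            alphaSecondary > 0, alphaSecondary < 1,
            nBoot >= 100, pressoNSim >= 1000)
  cfg <- list(exposureFile = exposureFile, outcomes = outcomes,
              exclusionFile = exclusionFile, methods = methods,
              seOrder = seOrder, nBoot = nBoot, pressoNSim = pressoNSim,
              seed = as.integer(seed), alphaPrimary = alphaPrimary,
              alphaSecondary = alphaSecondary,
              palindromePolicy = palindromePolicy, columnMap = columnMap)
  class(cfg) <- c("StudyConfig", "list")
  cfg
}

#' Read a study configuration from YAML
#'
#' The YAML file holds the [studyConfig()] arguments verbatim, e.g.
#' ```yaml
#' exposureFile: exposure.tsv
#' outcomes:
#'   - {label: ischemic_stroke, file: is.tsv, tier: primary}
#' exclusionFile: pleiotropic.txt
#' seed: 7
#' ```
#'
#' @param path YAML file path.
#' @param ... overrides applied on top of the file's values.
#' @return a `StudyConfig`.
#' @export
readStudyConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(studyConfig, vals)
}

## Skip-reason placeholder used in place of an MREstimate.
.skip <- function(reason) structure(list(reason = reason), class = "mrSkip")

.analyzeOutcome <- function(x, cfg, exclusions, methodSeeds) {
  est <- list()
  run <- function(tag, minSnps, fn) {
    if (!tag %in% cfg$methods) return(NULL)
    est[[tag]] <<- if (length(x) < minSnps)
      .skip(sprintf("requires >= %d SNPs, have %d", minSnps, length(x)))
    else fn()
  }
  run("ivw_fixed", 1L, function() mrIVW(x, seOrder = cfg$seOrder))
  if ("ivw_excl_pleiotropy" %in% cfg$methods) {
    est[["ivw_excl_pleiotropy"]] <- if (is.null(exclusions))
      .skip("no exclusion list supplied")
    else {
      xs <- applyExclusions(x, exclusions)
      if (length(xs) < 1L) .skip("exclusions removed every instrument")
      else mrIVW(xs, seOrder = cfg$seOrder, method = "ivw_excl_pleiotropy")
    }
  }
  run("egger", 3L, function() mrEgger(x, seOrder = cfg$seOrder))

  presso <- NULL
  wantPresso <- any(c("presso_raw", "presso_outlier_corrected") %in%
                      cfg$methods)
  if (wantPresso) {
    if (length(x) < 4L) {
      reason <- sprintf("requires >= 4 SNPs, have %d", length(x))
      if ("presso_raw" %in% cfg$methods)
        est[["presso_raw"]] <- .skip(reason)
      if ("presso_outlier_corrected" %in% cfg$methods)
        est[["presso_outlier_corrected"]] <- .skip(reason)
    } else {
      ## PRESSO keeps its own first-order residual weighting (see mrPresso)
      presso <- mrPresso(x, nSim = cfg$pressoNSim,
                         seed = methodSeeds["presso"])
      if ("presso_raw" %in% cfg$methods)
        est[["presso_raw"]] <- presso@estimateRaw
      if ("presso_outlier_corrected" %in% cfg$methods)
        est[["presso_outlier_corrected"]] <-
          presso@estimateCorrected %||% .skip("no outliers detected")
    }
  }
  run("weighted_median", 3L, function()
    mrWeightedMedian(x, nBoot = cfg$nBoot, seed = methodSeeds["median"],
                     seOrder = cfg$seOrder))
  run("weighted_mode", 3L, function()
    mrWeightedMode(x, nBoot = cfg$nBoot, seed = methodSeeds["mode"],
                   seOrder = cfg$seOrder))

  diagnostics <- list(
    heterogeneity = if (length(x) >= 2) cochranQ(x, seOrder = cfg$seOrder),
    rucker = if (length(x) >= 3) ruckerModelSelection(x, seOrder = cfg$seOrder),
    i2gx = if (length(x) >= 2) i2GX(x),
    presso = presso)
  strength <- tryCatch(instrumentStrength(x), error = function(e) NULL)
  list(estimates = est[intersect(.METHOD_ORDER, names(est))],
       diagnostics = diagnostics, strength = strength)
}

#' Run a full multi-outcome Mendelian randomization study
#'
#' Orchestrates the complete analysis described by a [studyConfig()]: for
#' each outcome the exposure and outcome tables are harmonized, instrument
#' strength summarized, every requested estimator run (including the
#' exclusion-sensitivity IVW when a list is supplied and both MR-PRESSO
#' estimates), the pleiotropy diagnostics computed, and significance called
#' at the outcome's tier threshold. A failing outcome is recorded as a
#' per-outcome error; the others still run. The report is deterministic given
#' the config's seed.
#'
#' @param config a `StudyConfig` from [studyConfig()] or [readStudyConfig()].
#' @return a [StudyReport-class].
#' @seealso [renderForestTable()], [writeStudyReport()].
#' @export
runStudy <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  exposure <- readAssociationTable(config$exposureFile,
                                   columnMap = config$columnMap,
                                   traitScale = "sd")
  exclusions <- if (!is.null(config$exclusionFile))
    readExclusionList(config$exclusionFile)
  nOut <- length(config$outcomes)
  seedMat <- withSeed(config$seed,
    matrix(sample.int(.Machine$integer.max - 1, nOut * 3), nOut, 3,
           dimnames = list(NULL, c("median", "mode", "presso"))))

  results <- list()
  for (i in seq_len(nOut)) {
    oc <- config$outcomes[[i]]
    alpha <- if (oc$tier == "primary") config$alphaPrimary
             else config$alphaSecondary
    entry <- tryCatch({
      outcome <- readAssociationTable(oc$file, columnMap = config$columnMap,
                                      traitScale = "log_or",
                                      label = oc$label)
      x <- harmonize(exposure, outcome,
                     palindromePolicy = config$palindromePolicy,
                     outcomeLabel = oc$label)
      res <- .analyzeOutcome(x, config, exclusions, seedMat[i, ])
      sig <- lapply(res$estimates, function(e)
        if (methods::is(e, "MREstimate")) mrPval(e) < alpha else NA)
      c(res, list(instrumentSet = x, tier = oc$tier, alpha = alpha,
                  significant = sig))
    }, error = function(e)
      list(error = conditionMessage(e), tier = oc$tier, alpha = alpha))
    results[[oc$label]] <- entry
  }
  new("StudyReport", outcomes = results, config = unclass(config),
      metadata = list(
        packageVersion = as.character(utils::packageVersion("plateletMR")),
        seed = config$seed,
        methodSeeds = seedMat))
}

#' Forest-plot-ready summary table of a study report
#'
#' One row per (outcome, method) in the canonical seven-method order, with
#' odds ratios per SD-unit increase of the exposure, 95% CI bounds, p-values
#' and the tier significance call. Skipped methods keep their row with the
#' skip reason in `note`.
#'
#' @param report a [StudyReport-class].
#' @return data.frame.
#' @export
renderForestTable <- function(report) {
  stopifnot(methods::is(report, "StudyReport"))
  methodsWanted <- report@config$methods
  rows <- list()
  for (label in names(report@outcomes)) {
    oc <- report@outcomes[[label]]
    for (m in intersect(.METHOD_ORDER, methodsWanted)) {
      e <- if (is.null(oc$error)) oc$estimates[[m]] else NULL
      row <- data.frame(outcome = label, tier = oc$tier, method = m,
                        n_snps = NA_integer_, or = NA_real_,
                        or_ci_low = NA_real_, or_ci_high = NA_real_,
                        pval = NA_real_, significant = NA,
                        note = "", stringsAsFactors = FALSE)
      if (!is.null(oc$error)) {
        row$note <- paste("outcome failed:", oc$error)
      } else if (inherits(e, "mrSkip")) {
        row$note <- paste("skipped:", e$reason)
      } else if (methods::is(e, "MREstimate")) {
        or <- mrOR(e)
        row$n_snps <- nSnps(e)
        row$or <- or[["or"]]
        row$or_ci_low <- or[["ci_low"]]
        row$or_ci_high <- or[["ci_high"]]
        row$pval <- mrPval(e)
        row$significant <- isTRUE(oc$significant[[m]])
      } else next  # method not requested for this outcome
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Diagnostics summary, one row per outcome.
.diagnosticsTable <- function(report) {
  rows <- lapply(names(report@outcomes), function(label) {
    oc <- report@outcomes[[label]]
    row <- data.frame(outcome = label, q = NA_real_, q_df = NA_real_,
                      q_pval = NA_real_, i2_mr = NA_real_,
                      het_flag = NA, q_prime = NA_real_,
                      model_test_p = NA_real_, egger_preferred = NA,
                      i2_gx = NA_real_, presso_global_p = NA_real_,
                      presso_outliers = "", distortion_p = NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(oc$error)) return(row)
    d <- oc$diagnostics
    if (!is.null(d$heterogeneity)) {
      row$q <- d$heterogeneity@q; row$q_df <- d$heterogeneity@df
      row$q_pval <- d$heterogeneity@pval; row$i2_mr <- d$heterogeneity@i2MR
      row$het_flag <- d$heterogeneity@flagPleiotropy
    }
    if (!is.null(d$rucker)) {
      row$q_prime <- d$rucker@qPrime
      row$model_test_p <- d$rucker@pModelTest
      row$egger_preferred <- d$rucker@eggerPreferred
    }
    if (!is.null(d$i2gx)) row$i2_gx <- d$i2gx@i2GX
    if (!is.null(d$presso)) {
      row$presso_global_p <- d$presso@globalPval
      row$presso_outliers <- paste(d$presso@outliers, collapse = ",")
      row$distortion_p <- d$presso@distortionPval
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write study report artifacts
#'
#' Writes `forest.tsv` (the [renderForestTable()] output),
#' `diagnostics.tsv`, `report.json` (full machine-readable report) and
#' `manifest.txt` (run audit log: harmonization dispositions, exclusions,
#' seeds) into `dir`.
#'
#' @param report a [StudyReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  forest <- renderForestTable(report)
  utils::write.table(forest, file.path(dir, "forest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(.diagnosticsTable(report),
                     file.path(dir, "diagnostics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  json <- list(metadata = report@metadata,
               config = report@config[setdiff(names(report@config),
                                              "columnMap")],
               forest = forest,
               diagnostics = .diagnosticsTable(report))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  lines <- c(sprintf("plateletMR %s", report@metadata$packageVersion),
             sprintf("master seed: %d", report@metadata$seed))
  for (label in names(report@outcomes)) {
    oc <- report@outcomes[[label]]
    lines <- c(lines, sprintf("outcome %s [%s tier, alpha=%g]:",
                              label, oc$tier, oc$alpha))
    if (!is.null(oc$error)) {
      lines <- c(lines, paste("  FAILED:", oc$error))
      next
    }
    prov <- provenance(oc$instrumentSet)
    lines <- c(lines,
      sprintf("  rsid intersection: %d", prov$nIntersect),
      sprintf("  dispositions: %s",
              paste(names(prov$dispositions), unlist(prov$dispositions),
                    sep = "=", collapse = ", ")),
      sprintf("  sign flips: %d", prov$nFlipped))
    for (ex in prov$exclusions)
      lines <- c(lines, sprintf("  exclusions: requested=%d removed=%d",
                                ex$nRequested, ex$nRemoved))
  }
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}
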