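#' @include AllClasses.R AllGenerics.R utils.R
NULL

.STD_COLS <- c("rsid", "effect_allele", "other_allele", "eaf", "beta",
               "se", "pval", "n")
.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Read a GWAS summary-association table
#'
#' Reads a tab- or comma-delimited table of per-SNP summary associations (one
#' row per SNP), validates every row against the association invariants, and
#' returns a standardized data.frame ready for [harmonize()]. Alleles are
#' upper-cased; only single-base A/C/G/T alleles are accepted (the instrument
#' panel is SNPs, so indels are rejected). Duplicated rsIDs keep the row with
#' the smallest p-value; the discarded rows are noted in the attributes.
#'
#' @param path file path; the delimiter (tab or comma) is auto-detected from
#'   the header line unless `sep` is given.
#' @param columnMap named character vector mapping standard names (`rsid`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) to the
#'   file's column names. Defaults to the identity mapping. `eaf` and `n` are
#'   optional; all others must resolve to a present column.
#' @param traitScale `"sd"` for a continuous exposure in SD units or
#'   `"log_or"` for a binary outcome on the log odds-ratio scale. Stored as
#'   an attribute and carried into harmonization provenance.
#' @param label trait name (defaults to the file name).
#' @param permissive if `FALSE` (default) any invalid row aborts the read
#'   with row-indexed diagnostics; if `TRUE` invalid rows are dropped and the
#'   diagnostics are attached as attribute `"rejected"`.
#' @param sep optional explicit field separator.
#' @return data.frame with the standard columns, plus attributes
#'   `traitScale`, `label`, `rejected` (data.frame of row, rsid, reason) and
#'   `duplicates` (rsids of discarded duplicate rows).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("rsid\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
#'              "rs1\ta\tg\t0.3\t0.05\t0.004\t1e-35\t166066"), tf)
#' readAssociationTable(tf, traitScale = "sd")
#' @export
readAssociationTable <- function(path, columnMap = NULL,
                                 traitScale = c("sd", "log_or"),
                                 label = basename(path), permissive = FALSE,
                                 sep = NULL) {
  traitScale <- match.arg(traitScale)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character")
  map <- stats::setNames(.STD_COLS, .STD_COLS)
  if (!is.null(columnMap)) {
    bad <- setdiff(names(columnMap), .STD_COLS)
    if (length(bad))
      stop("columnMap has unknown standard names: ", paste(bad, collapse = ", "))
    map[names(columnMap)] <- columnMap
  }
  required <- setdiff(.STD_COLS, c("eaf", "n"))
  absent <- required[!map[required] %in% names(raw)]
  if (length(absent))
    stop("mapped column(s) missing from ", path, ": ",
         paste(map[absent], collapse = ", "))
  get_col <- function(std) {
    if (map[[std]] %in% names(raw)) raw[[map[[std]]]] else NA_character_
  }
  suppressWarnings(df <- data.frame(
    rsid = get_col("rsid"),
    effect_allele = toupper(trimws(get_col("effect_allele"))),
    other_allele = toupper(trimws(get_col("other_allele"))),
    eaf = as.numeric(get_col("eaf")),
    beta = as.numeric(get_col("beta")),
    se = as.numeric(get_col("se")),
    pval = as.numeric(get_col("pval")),
    n = as.numeric(get_col("n")),
    stringsAsFactors = FALSE))

  eafGiven <- !is.na(get_col("eaf"))
  reasons <- character(nrow(df))
  addReason <- function(bad, why) {
    ifelse(bad & !nzchar(reasons), why, reasons)
  }
  okAllele <- function(a) a %in% names(.COMPLEMENT)
  reasons <- addReason(!nzchar(df$rsid) | is.na(df$rsid), "missing rsid")
  reasons <- addReason(!okAllele(df$effect_allele) | !okAllele(df$other_allele),
                       "allele not a single A/C/G/T base")
  reasons <- addReason(df$effect_allele == df$other_allele,
                       "effect and other allele identical")
  reasons <- addReason(!is.finite(df$beta), "malformed beta")
  reasons <- addReason(!is.finite(df$se) | df$se <= 0, "se must be > 0")
  reasons <- addReason(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1,
                       "pval outside (0, 1]")
  reasons <- addReason(eafGiven & (!is.finite(df$eaf) | df$eaf <= 0 | df$eaf >= 1),
                       "eaf outside (0, 1)")
  reasons <- addReason(!is.na(df$n) & df$n <= 0, "non-positive sample size")

  bad <- nzchar(reasons)
  rejected <- data.frame(row = which(bad), rsid = df$rsid[bad],
                         reason = reasons[bad], stringsAsFactors = FALSE)
  if (nrow(rejected) && !permissive)
    stop("invalid rows in ", path, " (set permissive = TRUE to drop them):\n",
         paste(sprintf("  row %d [%s]: %s", rejected$row, rejected$rsid,
                       rejected$reason), collapse = "\n"))
  df <- df[!bad, , drop = FALSE]

  dupDropped <- character(0)
  if (anyDuplicated(df$rsid)) {
    ord <- order(df$rsid, df$pval)  # smallest p first within rsid
    keepIdx <- ord[!duplicated(df$rsid[ord])]
    dupDropped <- df$rsid[setdiff(seq_len(nrow(df)), keepIdx)]
    message("dropped ", length(dupDropped),
            " duplicated rsID row(s), keeping smallest p-value")
    df <- df[sort(keepIdx), , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "traitScale") <- traitScale
  attr(df, "label") <- label
  attr(df, "rejected") <- rejected
  attr(df, "duplicates") <- unique(dupDropped)
  df
}

#' Read a plain-text rsID exclusion list
#'
#' One rsID per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of rsIDs.
#' @export
readExclusionList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns SNP-outcome effects onto the exposure's effect allele so that per-SNP
#' Wald ratios are computed on a shared allele. SNPs present in only one table
#' are dropped. When the outcome's alleles are swapped relative to the
#' exposure, the outcome beta is sign-flipped and its frequency replaced by
#' `1 - eaf`; strand-complement codings (e.g. A/G vs T/C) are resolved by
#' complementing before alignment. Palindromic SNPs (A/T, C/G), whose strand
#' cannot be resolved from alleles alone, are handled per
#' `palindromePolicy`:
#' \describe{
#'   \item{infer_by_eaf}{(default) align by comparing allele frequencies;
#'     dropped as ambiguous when either frequency lies inside
#'     `ambiguityWindow` or is missing.}
#'   \item{drop}{always removed.}
#'   \item{keep}{assumed to be reported on the same strand.}
#' }
#' Irreconcilable allele pairs (e.g. A/G vs A/C) are dropped with an
#' `allele_mismatch` disposition. All dispositions are counted in the
#' returned provenance; kept plus dropped counts always sum to the rsID
#' intersection.
#'
#' @param exposure,outcome standardized association data.frames from
#'   [readAssociationTable()] (or any data.frame with those columns).
#' @param palindromePolicy one of `"infer_by_eaf"`, `"drop"`, `"keep"`.
#' @param ambiguityWindow frequency window within which a palindromic SNP's
#'   strand cannot be inferred; default `c(0.42, 0.58)`.
#' @param exposureLabel,outcomeLabel trait names (default: the tables' label
#'   attributes).
#' @return an [InstrumentSet-class] whose provenance records the disposition
#'   counts (`kept`, `allele_mismatch`, `palindromic_dropped`,
#'   `palindromic_ambiguous`), the number of sign flips, and the SNPs absent
#'   from either side.
#' @export
harmonize <- function(exposure, outcome,
                      palindromePolicy = c("infer_by_eaf", "drop", "keep"),
                      ambiguityWindow = c(0.42, 0.58),
                      exposureLabel = NULL, outcomeLabel = NULL) {
  palindromePolicy <- match.arg(palindromePolicy)
  exposureLabel <- exposureLabel %||% attr(exposure, "label") %||% "exposure"
  outcomeLabel <- outcomeLabel %||% attr(outcome, "label") %||% "outcome"
  if (!nrow(exposure) || !nrow(outcome))
    stop("both exposure and outcome tables must be non-empty")

  shared <- intersect(exposure$rsid, outcome$rsid)
  if (!length(shared))
    stop("no shared rsIDs between exposure and outcome tables")
  ex <- exposure[match(shared, exposure$rsid), ]
  out <- outcome[match(shared, outcome$rsid), ]

  comp <- .COMPLEMENT
  pal <- ex$effect_allele == comp[ex$other_allele]
  sameExact <- out$effect_allele == ex$effect_allele &
    out$other_allele == ex$other_allele
  swapExact <- out$effect_allele == ex$other_allele &
    out$other_allele == ex$effect_allele
  sameComp <- comp[out$effect_allele] == ex$effect_allele &
    comp[out$other_allele] == ex$other_allele
  swapComp <- comp[out$effect_allele] == ex$other_allele &
    comp[out$other_allele] == ex$effect_allele

  ## literal alignment sign: +1 same, -1 swapped, NA irreconcilable.
  ## For palindromic SNPs exact and complement matches coincide, so the
  ## literal reading (exact match) is used as the starting point.
  sign0 <- rep(NA_real_, length(shared))
  sign0[sameExact | (!pal & sameComp)] <- 1
  sign0[swapExact | (!pal & swapComp)] <- -1

  disposition <- rep("kept", length(shared))
  disposition[is.na(sign0)] <- "allele_mismatch"

  isPal <- pal & !is.na(sign0)
  if (palindromePolicy == "drop") {
    disposition[isPal] <- "palindromic_dropped"
  } else if (palindromePolicy == "infer_by_eaf") {
    eafOut <- ifelse(sign0 == -1, 1 - out$eaf, out$eaf)
    ambiguous <- isPal & (is.na(ex$eaf) | is.na(eafOut) |
      (ex$eaf >= ambiguityWindow[1] & ex$eaf <= ambiguityWindow[2]) |
      (eafOut >= ambiguityWindow[1] & eafOut <= ambiguityWindow[2]))
    disposition[ambiguous] <- "palindromic_ambiguous"
    ## frequencies on the aligned allele should agree in direction; if not,
    ## the outcome is on the opposite strand -> flip once more
    strandFlip <- isPal & !ambiguous &
      ((ex$eaf < 0.5) != (eafOut < 0.5))
    sign0[strandFlip] <- -sign0[strandFlip]
  }
  ## palindromePolicy == "keep": literal alignment stands

  kept <- disposition == "kept"
  flip <- kept & sign0 == -1
  counts <- table(factor(disposition,
                         levels = c("kept", "allele_mismatch",
                                    "palindromic_dropped",
                                    "palindromic_ambiguous")))

  set <- InstrumentSet(
    rsid = shared[kept],
    betaX = ex$beta[kept], seX = ex$se[kept],
    betaY = (out$beta * sign0)[kept], seY = out$se[kept],
    eafX = ex$eaf[kept], nX = ex$n[kept],
    alignedAllele = ex$effect_allele[kept],
    flipped = flip[kept],
    exposureLabel = exposureLabel, outcomeLabel = outcomeLabel,
    provenance = list(
      palindromePolicy = palindromePolicy,
      ambiguityWindow = ambiguityWindow,
      nIntersect = length(shared),
      dispositions = as.list(counts),
      nFlipped = sum(flip),
      exposureOnly = setdiff(exposure$rsid, shared),
      outcomeOnly = setdiff(outcome$rsid, shared),
      exclusions = list()))
  if (!length(set))
    stop("harmonization left zero usable instruments")
  set
}

#' @describeIn applyExclusions remove instruments by rsID; unknown rsIDs are
#'   recorded in the provenance note and otherwise ignored.
setMethod("applyExclusions", "InstrumentSet", function(x, rsids) {
  rsids <- unique(as.character(rsids))
  df <- x@instruments
  hit <- df$rsid %in% rsids
  unknown <- setdiff(rsids, df$rsid)
  if (length(unknown))
    message(length(unknown), " exclusion rsID(s) not present in the set; ignored")
  prov <- x@provenance
  prov$exclusions <- c(prov$exclusions,
                       list(list(nRequested = length(rsids),
                                 nRemoved = sum(hit),
                                 unknown = unknown)))
  initialize(x, instruments = df[!hit, , drop = FALSE], provenance = prov)
})

#' Write a harmonized instrument table to TSV
#'
#' Serializes the instrument table of an [InstrumentSet-class] for audit.
#' The written file can be re-read with `read.delim`.
#'
#' @param x an [InstrumentSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeInstrumentTable <- function(x, path) {
  stopifnot(methods::is(x, "InstrumentSet"))
  utils::write.table(x@instruments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
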