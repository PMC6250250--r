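# Programmatic fixtures shared across test files.

# Minimal instrument set from raw vectors.
makeSet <- function(betaX, seX, betaY, seY,
                    rsid = sprintf("rs%03d", seq_along(betaX)), ...) {
  InstrumentSet(rsid = rsid, betaX = betaX, seX = seX,
                betaY = betaY, seY = seY, ...)
}

# Wald-ratio table from raw theta/se vectors.
makeRatios <- function(theta, se, rsid = sprintf("rs%03d", seq_along(theta))) {
  data.frame(rsid = rsid, theta = theta, se = se, weight = se^-2,
             stringsAsFactors = FALSE)
}

# Write a standard association table to a temp file, returning the path.
writeAssocFile <- function(df, sep = "\t", ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# A small well-formed exposure-style table.
assocTable <- function(n = 3, rsid = sprintf("rs%d", seq_len(n))) {
  data.frame(rsid = rsid,
             effect_allele = rep_len(c("A", "C", "G"), n),
             other_allele = rep_len(c("G", "T", "A"), n),
             eaf = seq(0.2, 0.4, length.out = n),
             beta = seq(0.05, 0.15, length.out = n),
             se = rep(0.01, n),
             pval = rep(1e-20, n),
             n = rep(166066, n),
             stringsAsFactors = FALSE)
}

# Simulated panel harmonized into an InstrumentSet.
simPanel <- function(seed, ...) {
  sim <- simulateTwoSample(simConfig(seed = seed, ...))
  harmonize(sim$exposure, sim$outcome)
}

# Builds a small synthetic study on disk: one exposure file, one or more
# outcome files (same panel, differing true effects), plus an exclusion list.
makeStudyFiles <- function(dir, thetas, tiers, jSnps = 80L, seed = 5,
                           nExclusions = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- names(thetas)
  outcomes <- list()
  exposurePath <- file.path(dir, "exposure.tsv")
  for (i in seq_along(thetas)) {
    # same seed, different thetaTrue: identical exposure draws, outcome
    # effects shifted by the causal signal only
    sim <- simulateTwoSample(simConfig(jSnps = jSnps, seed = seed,
                                       thetaTrue = thetas[[i]]))
    if (i == 1L)
      utils::write.table(sim$exposure, exposurePath, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    path <- file.path(dir, paste0(labels[i], ".tsv"))
    utils::write.table(sim$outcome, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outcomes[[i]] <- list(label = labels[i], file = path, tier = tiers[i])
  }
  exclusionPath <- file.path(dir, "exclusions.txt")
  rsids <- utils::read.delim(exposurePath)$rsid
  writeLines(c("# synthetic pleiotropic SNPs",
               utils::head(rsids, nExclusions)), exclusionPath)
  list(exposure = exposurePath, outcomes = outcomes,
       exclusions = exclusionPath)
}

# Scenario used for outlier/PRESSO studies: a 50-SNP candidate panel with h2
# scaled from the 219-SNP default so per-SNP instrument strength stays
# realistic; selection (the generator default) keeps only genome-wide
# significant instruments, as in the published panel. The retained J <= 50
# also keeps the Bonferroni floor of the add-one outlier p-values below the
# 0.05 threshold at nSim = 1000.
smallPanelConfig <- function(seed, ...) {
  simConfig(jSnps = 50L, h2Instruments = 0.035, thetaTrue = 0.1,
            seed = seed, ...)
}
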