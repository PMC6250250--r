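test_that("well-formed tables parse with normalized alleles", {
  df <- assocTable(3)
  df$effect_allele <- c("a", "c", "g")  # lower case in the file
  df$other_allele <- c("g", "t", "a")
  path <- writeAssocFile(df)
  out <- readAssociationTable(path, traitScale = "sd")
  expect_equal(nrow(out), 3)
  expect_equal(out$effect_allele, c("A", "C", "G"))
  expect_equal(out$beta, df$beta)
  expect_equal(attr(out, "traitScale"), "sd")
  expect_equal(nrow(attr(out, "rejected")), 0)

  # comma-delimited variant is auto-detected
  csv <- writeAssocFile(assocTable(3), sep = ",", ext = ".csv")
  expect_equal(nrow(readAssociationTable(csv, traitScale = "log_or")), 3)
})

test_that("invalid rows are rejected with row-indexed diagnostics", {
  df <- assocTable(4)
  df$se[2] <- 0                       # invariant violation
  df$effect_allele[3] <- "AT"         # indel-like allele
  path <- writeAssocFile(df)
  err <- expect_error(readAssociationTable(path, traitScale = "sd"))
  expect_match(conditionMessage(err), "rs2")
  expect_match(conditionMessage(err), "se must be > 0")

  out <- readAssociationTable(path, traitScale = "sd", permissive = TRUE)
  expect_equal(nrow(out), 2)
  rej <- attr(out, "rejected")
  expect_setequal(rej$rsid, c("rs2", "rs3"))
  expect_setequal(rej$row, c(2L, 3L))
})

test_that("missing mapped columns are a configuration error", {
  df <- assocTable(2)
  names(df)[names(df) == "beta"] <- "effect_size"
  path <- writeAssocFile(df)
  expect_error(readAssociationTable(path, traitScale = "sd"),
               "missing.*beta")
  out <- readAssociationTable(path, traitScale = "sd",
                              columnMap = c(beta = "effect_size"))
  expect_equal(out$beta, df$effect_size)
})

test_that("duplicated rsIDs keep the smallest p-value row", {
  df <- assocTable(3, rsid = c("rs1", "rs1", "rs2"))
  df$pval <- c(1e-10, 1e-30, 1e-9)
  df$beta <- c(0.05, 0.10, 0.15)
  path <- writeAssocFile(df)
  expect_message(out <- readAssociationTable(path, traitScale = "sd"),
                 "duplicated")
  expect_equal(nrow(out), 2)
  expect_equal(out$beta[out$rsid == "rs1"], 0.10)
})

test_that("harmonization aligns, flips and drops as specified", {
  ex <- assocTable(5, rsid = paste0("rs", 1:5))
  ex$effect_allele <- c("A", "A", "A", "A", "A")
  ex$other_allele <- c("G", "G", "G", "T", "G")
  ex$eaf <- c(0.3, 0.3, 0.3, 0.10, 0.3)
  ex$beta <- rep(0.1, 5)
  out <- ex
  out$beta <- rep(0.05, 5)
  # rs1 identical; rs2 swapped alleles; rs3 strand complement (T/C);
  # rs4 palindromic with concordance-breaking eaf; rs5 irreconcilable
  out$effect_allele <- c("A", "G", "T", "A", "A")
  out$other_allele <- c("G", "A", "C", "T", "C")
  out$eaf <- c(0.3, 0.7, 0.3, 0.89, 0.3)

  x <- harmonize(ex, out, palindromePolicy = "infer_by_eaf")
  df <- instruments(x)
  expect_setequal(df$rsid, c("rs1", "rs2", "rs3", "rs4"))
  expect_equal(df$beta_y[df$rsid == "rs1"], 0.05)   # identity alignment
  expect_false(df$flipped[df$rsid == "rs1"])
  expect_equal(df$beta_y[df$rsid == "rs2"], -0.05)  # sign flip
  expect_true(df$flipped[df$rsid == "rs2"])
  expect_equal(df$beta_y[df$rsid == "rs3"], 0.05)   # strand only, no flip
  expect_equal(df$beta_y[df$rsid == "rs4"], -0.05)  # palindrome via eaf
  expect_true(df$flipped[df$rsid == "rs4"])

  prov <- provenance(x)
  expect_equal(prov$dispositions$allele_mismatch, 1)
  # disposition counts sum to the rsid intersection
  expect_equal(sum(unlist(prov$dispositions)), prov$nIntersect)
})

test_that("palindrome policies behave per contract", {
  ex <- assocTable(3, rsid = c("rs1", "rs2", "rs3"))
  ex$effect_allele <- c("A", "C", "A")
  ex$other_allele <- c("T", "G", "G")   # rs1, rs2 palindromic; rs3 not
  ex$eaf <- c(0.10, 0.50, 0.30)
  out <- ex
  out$beta <- c(0.02, 0.03, 0.04)
  out$eaf <- c(0.11, 0.50, 0.30)

  dropped <- harmonize(ex, out, palindromePolicy = "drop",
                       exposureLabel = "x", outcomeLabel = "y")
  expect_equal(instruments(dropped)$rsid, "rs3")
  expect_equal(provenance(dropped)$dispositions$palindromic_dropped, 2)

  kept <- harmonize(ex, out, palindromePolicy = "keep")
  expect_equal(length(kept), 3)
  expect_false(any(instruments(kept)$flipped))

  inferred <- harmonize(ex, out, palindromePolicy = "infer_by_eaf")
  df <- instruments(inferred)
  expect_setequal(df$rsid, c("rs1", "rs3"))  # rs2 ambiguous at eaf 0.5
  expect_false(any(df$flipped))              # concordant frequencies
  expect_equal(provenance(inferred)$dispositions$palindromic_ambiguous, 1)
})

test_that("harmonize is idempotent on aligned tables", {
  sim <- simulateTwoSample(simConfig(jSnps = 40, seed = 5))
  x1 <- harmonize(sim$exposure, sim$outcome)
  # feed the harmonized outcome back through as an association table
  df <- instruments(x1)
  out2 <- data.frame(rsid = df$rsid, effect_allele = df$aligned_allele,
                     other_allele = "G", eaf = df$eaf_x, beta = df$beta_y,
                     se = df$se_y, pval = 0.5, n = 1000,
                     stringsAsFactors = FALSE)
  x2 <- harmonize(sim$exposure, out2)
  expect_equal(instruments(x2)$beta_y, df$beta_y)
  expect_equal(instruments(x2)$flipped, rep(FALSE, nrow(df)))
})

test_that("Wald ratios are invariant to input allele orientation", {
  sim <- simulateTwoSample(simConfig(jSnps = 60, seed = 9))
  base <- waldRatios(harmonize(sim$exposure, sim$outcome))
  for (rep in 1:3) {
    set.seed(100 + rep)
    ex <- sim$exposure
    flip <- runif(nrow(ex)) < 0.5
    ex[flip, c("effect_allele", "other_allele")] <-
      ex[flip, c("other_allele", "effect_allele")]
    ex$beta[flip] <- -ex$beta[flip]
    ex$eaf[flip] <- 1 - ex$eaf[flip]
    reoriented <- waldRatios(harmonize(ex, sim$outcome))
    expect_equal(reoriented$theta[order(reoriented$rsid)],
                 base$theta[order(base$rsid)], tolerance = 1e-12)
  }
})

test_that("exclusion lists subset the panel without mutating the input", {
  x <- simPanel(seed = 3, jSnps = 230L, gwThreshold = NULL)
  x <- x[1:219]  # the published panel size
  excl <- instruments(x)$rsid[seq(2, 78, by = 2)]  # 39 pleiotropic SNPs
  expect_length(excl, 39)
  reduced <- applyExclusions(x, excl)
  expect_equal(length(reduced), 180)
  expect_equal(length(x), 219)  # original untouched

  expect_equal(length(applyExclusions(x, character(0))), 219)
  expect_message(noop <- applyExclusions(x, c("rs_nothere", "rs_ghost")),
                 "not present")
  expect_equal(length(noop), 219)
  expect_equal(provenance(noop)$exclusions[[1]]$unknown,
               c("rs_nothere", "rs_ghost"))
})

test_that("exclusion list files support comments and blanks", {
  path <- tempfile()
  writeLines(c("# pleiotropic SNPs", "rs1", "", "rs2  # trailing note", "rs1"),
             path)
  expect_setequal(readExclusionList(path), c("rs1", "rs2"))
})

test_that("instrument tables round-trip through TSV", {
  x <- simPanel(seed = 21, jSnps = 30L, gwThreshold = NULL)
  path <- tempfile(fileext = ".tsv")
  writeInstrumentTable(x, path)
  back <- utils::read.delim(path)
  expect_equal(back$beta_x, instruments(x)$beta_x)
  expect_equal(back$rsid, instruments(x)$rsid)
})
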