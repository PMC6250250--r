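test_that("identical ratios give zero heterogeneity", {
  r <- makeRatios(theta = rep(0.2, 4), se = c(0.1, 0.2, 0.1, 0.3))
  het <- cochranQ(r)
  expect_equal(het@q, 0)
  expect_equal(het@i2MR, 0)
  expect_equal(het@pval, 1)
  expect_false(het@flagPleiotropy)
})

test_that("Cochran Q matches the direct-summation oracle and metafor", {
  theta <- c(0.05, 0.3, -0.1)
  se <- c(0.08, 0.15, 0.12)
  het <- cochranQ(makeRatios(theta, se))
  pooled <- oracleIVW(theta, se)$beta
  expect_equal(het@q, oracleCochranQ(theta, se, pooled), tolerance = 1e-12)
  expect_equal(het@df, 2)

  mf <- metafor::rma(yi = theta, sei = se, method = "FE")
  expect_equal(het@q, mf$QE, tolerance = 1e-10)
  expect_equal(het@pval, mf$QEp, tolerance = 1e-10)

  # permutation invariance
  perm <- c(3, 1, 2)
  expect_equal(cochranQ(makeRatios(theta[perm], se[perm]))@q, het@q,
               tolerance = 1e-12)
})

test_that("heterogeneity flag requires both I2MR > 25% and p < 0.05", {
  # strong dispersion: both conditions met
  hot <- cochranQ(makeRatios(c(-1, 0, 1, 2), rep(0.05, 4)))
  expect_true(hot@i2MR > 25 && hot@pval < 0.05)
  expect_true(hot@flagPleiotropy)
  # mild dispersion: I2 above 25 is possible with non-significant p at J=2
  mild <- cochranQ(makeRatios(c(0.0, 0.25), rep(0.15, 2)))
  expect_gt(mild@i2MR, 25)
  expect_gt(mild@pval, 0.05)
  expect_false(mild@flagPleiotropy)
})

test_that("Rucker Q-prime vanishes on noiseless linear data", {
  set.seed(19)
  bx <- runif(5, 0.05, 0.2)
  x <- makeSet(bx, rep(0.004, 5), 0.002 + 0.1 * bx, rep(0.01, 5))
  sel <- ruckerModelSelection(x)
  expect_lt(sel@qPrime, 1e-16)
  expect_equal(sel@qMinusQPrime, sel@q, tolerance = 1e-10)
})

test_that("Rucker statistics match a residual-sum oracle on 4 points", {
  bx <- c(0.05, 0.09, 0.13, 0.2)
  by <- c(0.012, 0.002, 0.025, 0.014)
  x <- makeSet(bx, rep(0.004, 4), by, rep(0.008, 4))
  sel <- ruckerModelSelection(x)

  v <- waldRatios(x)$weight / bx^2
  wls <- oracleWLS(bx, by, v)
  expect_equal(sel@qPrime, wls$rss, tolerance = 1e-12)
  ivw <- oracleIVW(waldRatios(x)$theta, waldRatios(x)$se)
  resIVW <- by - ivw$beta * bx
  expect_equal(sel@q, sum(v * resIVW^2), tolerance = 1e-12)
  expect_equal(sel@pModelTest,
               pchisq(sel@q - sel@qPrime, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Q is never smaller than Q-prime (the Egger fit adds a parameter)", {
  set.seed(29)
  for (i in 1:20) {
    J <- sample(3:50, 1)
    x <- makeSet(runif(J, 0.01, 0.2), runif(J, 0.002, 0.01),
                 rnorm(J, 0, 0.03), runif(J, 0.005, 0.02))
    sel <- ruckerModelSelection(x)
    expect_gte(sel@q + 1e-10, sel@qPrime)
  }
})

test_that("the Egger-vs-IVW model test is calibrated under no pleiotropy", {
  hits <- 0
  nRep <- 400
  for (i in seq_len(nRep)) {
    x <- simPanel(seed = 5000 + i, jSnps = 50L, gwThreshold = NULL,
                  h2Instruments = 0.035)
    if (ruckerModelSelection(x)@eggerPreferred) hits <- hits + 1
  }
  expect_gt(hits / nRep, 0.01)
  expect_lt(hits / nRep, 0.10)
})

test_that("I2GX matches its direct-sum oracle and detects zero dispersion", {
  x0 <- makeSet(rep(0.1, 3), c(0.01, 0.02, 0.01),
                c(0.01, 0.02, 0.015), rep(0.01, 3))
  r0 <- i2GX(x0)
  expect_equal(r0@qGX, 0)
  expect_equal(r0@i2GX, 0)
  expect_false(r0@lowBiasFlag)

  bx <- c(0.04, 0.11, 0.2)
  sx <- c(0.004, 0.006, 0.005)
  x <- makeSet(bx, sx, c(0.01, 0.02, 0.015), rep(0.01, 3))
  res <- i2GX(x)
  oracle <- oracleIGX(bx, sx)
  expect_equal(res@qGX, oracle$q, tolerance = 1e-12)
  expect_equal(res@i2GX, oracle$i2, tolerance = 1e-12)
  expect_true(res@lowBiasFlag)  # dispersion >> measurement error here
})

test_that("I2 measures are invariant to rescaling a trait's units", {
  x <- simPanel(seed = 41, jSnps = 30L, gwThreshold = NULL)
  df <- instruments(x)
  c1 <- 3.7
  xScaledX <- InstrumentSet(df$rsid, c1 * df$beta_x, c1 * df$se_x,
                            df$beta_y, df$se_y)
  expect_equal(i2GX(xScaledX)@i2GX, i2GX(x)@i2GX, tolerance = 1e-10)
  xScaledY <- InstrumentSet(df$rsid, df$beta_x, df$se_x,
                            c1 * df$beta_y, c1 * df$se_y)
  expect_equal(cochranQ(xScaledY)@i2MR, cochranQ(x)@i2MR, tolerance = 1e-10)
  expect_equal(cochranQ(xScaledY)@q, cochranQ(x)@q, tolerance = 1e-10)
})

test_that("funnel and radial tables are plot-ready and order-preserving", {
  r1 <- makeRatios(0.3, 0.15)
  f1 <- funnelData(r1)
  expect_equal(nrow(f1), 1)
  expect_equal(f1$precision, 1 / 0.15)
  expect_equal(f1$pooled, 0.3)

  x <- simPanel(seed = 43, jSnps = 25L, gwThreshold = NULL)
  r <- waldRatios(x)
  fd <- funnelData(x)
  rd <- radialData(x)
  expect_equal(fd$rsid, r$rsid)  # input order preserved
  expect_equal(rd$rsid, r$rsid)

  # through-origin slope of the radial points equals the IVW estimate
  slopeFit <- sum(rd$sqrt_w * rd$theta_sqrt_w) / sum(rd$sqrt_w^2)
  expect_equal(slopeFit, mrBeta(mrIVW(x)), tolerance = 1e-12)
  expect_equal(rd$slope[1], mrBeta(mrIVW(x)), tolerance = 1e-12)

  # round-trips through TSV
  path <- tempfile(fileext = ".tsv")
  utils::write.table(fd, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(path)
  expect_equal(back$theta, fd$theta)
})
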