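test_that("single-SNP IVW is the Wald ratio itself", {
  r <- makeRatios(theta = 0.42, se = 0.1)
  fit <- mrIVW(r)
  expect_equal(mrBeta(fit), 0.42)
  expect_equal(mrSE(fit), 0.1)
  expect_equal(nSnps(fit), 1L)
})

test_that("equal-weight IVW reduces to the closed form t, s/sqrt(J)", {
  r <- makeRatios(theta = rep(0.3, 5), se = rep(0.2, 5))
  fit <- mrIVW(r)
  expect_equal(mrBeta(fit), 0.3)
  expect_equal(mrSE(fit), 0.2 / sqrt(5), tolerance = 1e-12)
})

test_that("IVW matches the brute-force oracle and metafor on a 3-SNP case", {
  theta <- c(0.2, 0.4, 0.6)
  se <- c(0.1, 0.2, 0.3)
  fit <- mrIVW(makeRatios(theta, se))
  oracle <- oracleIVW(theta, se)
  expect_equal(mrBeta(fit), oracle$beta, tolerance = 1e-12)
  expect_equal(mrSE(fit), oracle$se, tolerance = 1e-12)

  # independent cross-check against the meta-analysis fixed-effect fit
  mf <- metafor::rma(yi = theta, sei = se, method = "FE")
  expect_equal(mrBeta(fit), as.numeric(mf$beta), tolerance = 1e-10)
  expect_equal(mrSE(fit), mf$se, tolerance = 1e-10)
  expect_equal(unname(mrCI(fit)), c(mf$ci.lb, mf$ci.ub), tolerance = 1e-10)
  expect_equal(mrPval(fit), mf$pval, tolerance = 1e-10)
})

test_that("IVW lies within the ratio range and its SE shrinks with SNPs", {
  set.seed(42)
  for (i in 1:10) {
    J <- sample(3:30, 1)
    r <- makeRatios(theta = rnorm(J), se = runif(J, 0.05, 0.5))
    fit <- mrIVW(r)
    expect_gte(mrBeta(fit), min(r$theta))
    expect_lte(mrBeta(fit), max(r$theta))
    extra <- makeRatios(theta = c(r$theta, 0), se = c(r$se, 0.3))
    expect_lt(mrSE(mrIVW(extra)), mrSE(fit))
  }
})

test_that("MR-Egger recovers a noiseless line exactly", {
  set.seed(7)
  bx <- runif(6, 0.02, 0.2)
  a <- 0.003
  t <- 0.12
  x <- makeSet(bx, rep(0.005, 6), a + t * bx, rep(0.01, 6))
  fit <- mrEgger(x)
  expect_equal(mrBeta(fit), t, tolerance = 1e-10)
  expect_equal(mrExtras(fit)$intercept, a, tolerance = 1e-10)
  expect_lt(mrExtras(fit)$qPrime, 1e-18)
})

test_that("MR-Egger agrees with an lm() weighted-least-squares oracle", {
  set.seed(8)
  bx <- c(0.05, 0.09, 0.13, 0.2)
  by <- c(0.01, 0.004, 0.02, 0.017)
  x <- makeSet(bx, rep(0.004, 4), by, rep(0.008, 4))
  fit <- mrEgger(x)
  v <- waldRatios(x)$weight / bx^2
  oracle <- oracleWLS(bx, by, v)
  expect_equal(mrBeta(fit), oracle$slope, tolerance = 1e-12)
  expect_equal(mrExtras(fit)$intercept, oracle$intercept, tolerance = 1e-12)
  expect_equal(mrExtras(fit)$qPrime, oracle$rss, tolerance = 1e-12)

  # SEs: lm's residual-variance scaling replaced by the multiplicative
  # random-effects convention floored at 1
  s <- summary(stats::lm(by ~ bx, weights = v))
  disp <- max(1, oracle$rss / 2)
  expect_equal(mrSE(fit),
               s$coefficients["bx", "Std. Error"] / s$sigma * sqrt(disp),
               tolerance = 1e-10)
})

test_that("constraining the Egger intercept to zero recovers IVW", {
  set.seed(11)
  for (i in 1:5) {
    J <- sample(4:40, 1)
    x <- makeSet(runif(J, 0.02, 0.2), runif(J, 0.003, 0.01),
                 rnorm(J, 0, 0.02), runif(J, 0.005, 0.02))
    r <- waldRatios(x)
    v <- r$weight / instruments(x)$beta_x^2
    bx <- instruments(x)$beta_x
    by <- instruments(x)$beta_y
    constrained <- sum(v * bx * by) / sum(v * bx^2)
    expect_equal(constrained, mrBeta(mrIVW(x)), tolerance = 1e-12)
  }
})

test_that("weighted median walks the cumulative-weight formula", {
  # 3 equal weights: p hits 0.5 exactly at the middle order statistic
  fit <- mrWeightedMedian(makeRatios(c(1, 2, 3), rep(0.5, 3)),
                          nBoot = 200, seed = 1)
  expect_equal(mrBeta(fit), 2)

  # 4-SNP unequal-weight instance vs the hand-walk oracle
  theta <- c(0.1, 0.5, 0.3, 0.9)
  se <- c(0.05, 0.2, 0.1, 0.4)
  fit4 <- mrWeightedMedian(makeRatios(theta, se), nBoot = 200, seed = 1)
  expect_equal(mrBeta(fit4), oracleWeightedMedian(theta, se^-2),
               tolerance = 1e-12)
})

test_that("equal-weight weighted median equals the interpolated median", {
  set.seed(13)
  for (J in c(5, 8)) {
    theta <- rnorm(J)
    fit <- mrWeightedMedian(makeRatios(theta, rep(0.1, J)),
                            nBoot = 200, seed = 2)
    expect_equal(mrBeta(fit), stats::median(theta), tolerance = 1e-12)
  }
})

test_that("degenerate ratios give the common value with small bootstrap SE", {
  r <- makeRatios(theta = rep(0.25, 6), se = rep(0.001, 6))
  med <- mrWeightedMedian(r, nBoot = 300, seed = 4)
  expect_equal(mrBeta(med), 0.25)
  expect_lt(mrSE(med), 0.005)
  mode <- mrWeightedMode(r, nBoot = 300, seed = 4)
  expect_equal(mrBeta(mode), 0.25)
})

test_that("weighted mode finds the concordant cluster, matching the grid oracle", {
  theta <- c(0.09, 0.10, 0.11, 0.105, 0.095, 1.0, 1.05)
  se <- c(rep(0.02, 5), 0.3, 0.3)
  w <- se^-2
  fit <- mrWeightedMode(makeRatios(theta, se), nBoot = 200, seed = 5)
  expect_equal(mrBeta(fit), oracleWeightedMode(theta, w), tolerance = 1e-12)
  expect_gt(mrBeta(fit), 0.05)
  expect_lt(mrBeta(fit), 0.15)
})

test_that("estimators are invariant to input order and orientation flips", {
  set.seed(17)
  x <- simPanel(seed = 23, jSnps = 40L, gwThreshold = NULL)
  df <- instruments(x)
  perm <- sample(nrow(df))
  xp <- x[perm]
  expect_equal(mrBeta(mrIVW(xp)), mrBeta(mrIVW(x)), tolerance = 1e-12)
  expect_equal(mrBeta(mrWeightedMode(xp, nBoot = 100, seed = 1)),
               mrBeta(mrWeightedMode(x, nBoot = 100, seed = 1)),
               tolerance = 1e-12)

  # flip the orientation of a random subset of SNPs
  flip <- runif(nrow(df)) < 0.5
  xf <- InstrumentSet(rsid = df$rsid,
                      betaX = ifelse(flip, -df$beta_x, df$beta_x),
                      seX = df$se_x,
                      betaY = ifelse(flip, -df$beta_y, df$beta_y),
                      seY = df$se_y)
  expect_equal(mrBeta(mrIVW(xf)), mrBeta(mrIVW(x)), tolerance = 1e-12)
  expect_equal(mrBeta(mrEgger(xf)), mrBeta(mrEgger(x)), tolerance = 1e-12)
  expect_equal(mrExtras(mrEgger(xf))$intercept,
               mrExtras(mrEgger(x))$intercept, tolerance = 1e-12)
  expect_equal(mrBeta(mrWeightedMedian(xf, nBoot = 100, seed = 2)),
               mrBeta(mrWeightedMedian(x, nBoot = 100, seed = 2)),
               tolerance = 1e-12)
})

test_that("odds-ratio fields are the exponential of the log scale", {
  x <- simPanel(seed = 31, jSnps = 30L, gwThreshold = NULL)
  fits <- list(mrIVW(x), mrEgger(x),
               mrWeightedMedian(x, nBoot = 100, seed = 3),
               mrWeightedMode(x, nBoot = 100, seed = 3))
  for (fit in fits) {
    or <- mrOR(fit)
    expect_equal(unname(or),
                 exp(c(mrBeta(fit), unname(mrCI(fit)))), tolerance = 1e-12)
    row <- as.data.frame(fit)
    expect_equal(row$or, exp(row$beta))
    expect_lte(row$or_ci_low, row$or)
  }
})

test_that("bootstrap standard errors are reproducible given a seed", {
  r <- waldRatios(simPanel(seed = 37, jSnps = 30L, gwThreshold = NULL))
  a <- mrWeightedMedian(r, nBoot = 300, seed = 99)
  b <- mrWeightedMedian(r, nBoot = 300, seed = 99)
  expect_identical(mrSE(a), mrSE(b))
  c1 <- mrWeightedMode(r, nBoot = 300, seed = 99)
  c2 <- mrWeightedMode(r, nBoot = 300, seed = 99)
  expect_identical(mrSE(c1), mrSE(c2))
  expect_false(identical(mrSE(a),
                         mrSE(mrWeightedMedian(r, nBoot = 300, seed = 100))))
})

test_that("estimator preconditions are enforced", {
  r2 <- makeRatios(c(0.1, 0.2), c(0.1, 0.1))
  expect_error(mrWeightedMedian(r2, nBoot = 200), "at least 3")
  expect_error(mrWeightedMode(r2, nBoot = 200), "at least 3")
  expect_error(mrWeightedMedian(makeRatios(c(1, 2, 3), rep(1, 3)),
                                nBoot = 50), "nBoot")
  expect_error(mrEgger(makeSet(c(0.1, 0.2), c(0.01, 0.01),
                               c(0.01, 0.02), c(0.01, 0.01))),
               "at least 3")
  expect_error(mrIVW(makeRatios(numeric(0), numeric(0))), "at least 1")
})
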