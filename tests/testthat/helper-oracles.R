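# Independent brute-force oracles. These deliberately avoid the package's
# code paths: explicit loops, lm() for weighted least squares, and direct
# evaluation of the defining formulas.

oracleIVW <- function(theta, se) {
  w <- 1 / se^2
  num <- 0
  den <- 0
  for (j in seq_along(theta)) {
    num <- num + w[j] * theta[j]
    den <- den + w[j]
  }
  list(beta = num / den, se = sqrt(1 / den))
}

# Weighted least squares of y on x via lm(); returns intercept, slope and the
# weighted residual sum of squares.
oracleWLS <- function(x, y, w) {
  fit <- stats::lm(y ~ x, weights = w)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       rss = sum(w * residuals(fit)^2))
}

oracleCochranQ <- function(theta, se, pooled) {
  q <- 0
  for (j in seq_along(theta)) q <- q + (theta[j] - pooled)^2 / se[j]^2
  q
}

oracleIGX <- function(bx, sx) {
  bx <- abs(bx)
  w <- 1 / sx^2
  bbar <- sum(w * bx) / sum(w)
  q <- 0
  for (j in seq_along(bx)) q <- q + w[j] * (bx[j] - bbar)^2
  i2 <- if (q > 0) max(0, (q - (length(bx) - 1)) / q) * 100 else 0
  list(q = q, i2 = i2)
}

# Walks the standardized cumulative weights p_j = (S_j - w_j/2)/S_J by hand
# and interpolates the crossing of 0.5 between adjacent order statistics.
oracleWeightedMedian <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  ww <- w[o]
  total <- sum(ww)
  running <- 0
  p <- numeric(length(th))
  for (j in seq_along(th)) {
    p[j] <- (running + ww[j] / 2) / total
    running <- running + ww[j]
  }
  if (p[1] >= 0.5) return(th[1])
  if (p[length(p)] <= 0.5) return(th[length(th)])
  for (j in seq_len(length(th) - 1)) {
    if (p[j] <= 0.5 && p[j + 1] >= 0.5) {
      return(th[j] + (0.5 - p[j]) * (th[j + 1] - th[j]) / (p[j + 1] - p[j]))
    }
  }
  stop("no crossing found")
}

# Dense-grid maximization of the weighted normal-kernel density under the
# same bandwidth and grid convention as the estimator, evaluated by an
# explicit double loop.
oracleWeightedMode <- function(theta, w, phi = 1, gridN = 512L) {
  s <- min(stats::sd(theta), stats::mad(theta))
  if (s <= 0) s <- stats::sd(theta)
  h <- phi * 0.9 * s * length(theta)^(-1 / 5)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = gridN)
  ww <- w / sum(w)
  best <- -Inf
  bestX <- NA_real_
  for (g in grid) {
    dens <- 0
    for (j in seq_along(theta))
      dens <- dens + ww[j] * stats::dnorm(g, mean = theta[j], sd = h)
    if (dens > best) {
      best <- dens
      bestX <- g
    }
  }
  bestX
}
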