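# Independent brute-force oracles for the agreement statistics: plain loops
# and explicit formulas, kept deliberately separate from the package's
# vectorized implementations.

oracle_dice <- function(a, b) {
  na <- 0; nb <- 0; nab <- 0
  for (i in seq_along(a)) {
    ia <- a[i] > 0; ib <- b[i] > 0
    na <- na + ia; nb <- nb + ib; nab <- nab + (ia && ib)
  }
  2 * nab / (na + nb)
}

oracle_ve <- function(vn, vg) (vn - vg) / ((vn + vg) / 2)

oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- 0; vy <- 0; cxy <- 0
  for (i in seq_len(n)) {
    vx <- vx + (x[i] - mx)^2
    vy <- vy + (y[i] - my)^2
    cxy <- cxy + (x[i] - mx) * (y[i] - my)
  }
  2 * (cxy / n) / (vx / n + vy / n + (mx - my)^2)
}

oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

oracle_bland_altman <- function(x, y) {
  d <- y - x
  n <- length(d)
  bias <- sum(d) / n
  s <- sqrt(sum((d - bias)^2) / (n - 1))
  list(bias = bias,
       ci95_bias = c(bias - 1.96 * s / sqrt(n), bias + 1.96 * s / sqrt(n)),
       loa = c(oracle_quantile7(d, 0.025), oracle_quantile7(d, 0.975)))
}

oracle_fit_nrmse <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxx <- sum((x - mx)^2); sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  yhat <- intercept + slope * x
  nrmse <- sqrt(sum((yhat - x)^2) / n) / mx
  pcc <- sxy / sqrt(sxx * sum((y - my)^2))
  srcc <- cor(rank(x), rank(y))
  list(slope = slope, intercept = intercept, nrmse = nrmse, pcc = pcc,
       srcc = srcc)
}
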