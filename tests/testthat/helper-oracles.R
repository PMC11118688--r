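# Independent brute-force oracles. These deliberately avoid the code paths
# (and, where possible, the library calls) used by the implementation.

# geometric mean via explicit exp-mean-log loop
oracleCollapse <- function(counts, gene, negative, floor = 0.5) {
  genes <- unique(gene[!negative])
  out <- matrix(NA_real_, length(genes), ncol(counts),
                dimnames = list(genes, colnames(counts)))
  for (g in genes) {
    idx <- which(gene == g & !negative)
    for (s in seq_len(ncol(counts))) {
      v <- pmax(counts[idx, s], floor)
      out[g, s] <- exp(sum(log(v)) / length(v))
    }
  }
  out
}

oracleLOQ <- function(negs, floor = 2, exponent = 2, zero_floor = 0.5) {
  lv <- log(pmax(negs, zero_floor))
  gm <- exp(mean(lv))
  gsd <- if (length(lv) > 1) exp(sqrt(sum((lv - mean(lv))^2) / (length(lv) - 1)))
         else 1
  max(floor, gm * gsd^exponent)
}

oracleQ3 <- function(vals) {
  q3 <- apply(vals, 2, function(v) unname(quantile(v, 0.75)))
  target <- exp(mean(log(q3)))
  sweep(vals, 2, q3 / target, "/")
}

# exhaustive hypergeometric upper tail via choose()
oracleHyperTail <- function(kmin, m, N, q) {
  if (kmin <= max(0, q - (N - m))) return(1)
  js <- kmin:min(m, q)
  if (!length(js)) return(0)
  sum(choose(m, js) * choose(N - m, q - js)) / choose(N, q)
}

# two-group log-rank statistic from an explicit risk table
oracleLogrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V, chisq = if (V > 0) (O - E)^2 / V else 0)
}

# Cox partial log-likelihood for a single binary covariate without ties,
# maximized on a grid
oracleCoxGrid <- function(time, event, x, grid = seq(-5, 5, by = 0.002)) {
  stopifnot(!anyDuplicated(time[event == 1]), all(x %in% c(0, 1)))
  ets <- time[event == 1]
  d1 <- sum(x[event == 1])
  eb <- exp(grid)
  ll <- grid * d1
  for (t in ets) {
    risk <- time >= t
    n1 <- sum(x[risk])
    n0 <- sum(risk) - n1
    ll <- ll - log(n0 + n1 * eb)
  }
  grid[which.max(ll)]
}

# OLS by explicit normal equations
oracleOLS <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
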