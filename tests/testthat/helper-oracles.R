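# Independent oracles, deliberately brute-force and separate from the
# package's computation paths.

# rank-sum U by direct pair counting (ties count one half)
brute_u <- function(first, last) {
  u <- 0
  for (y in last) for (x in first)
    u <- u + (y > x) + 0.5 * (y == x)
  u
}

# exact two-sided rank-sum p by enumerating every label assignment
exact_ranksum_p <- function(first, last) {
  pool <- c(first, last)
  n1 <- length(first)
  n <- length(pool)
  mu <- n1 * (n - n1) / 2
  obs <- abs(brute_u(first, last) - mu)
  idx <- utils::combn(n, n1)
  stats <- apply(idx, 2L, function(i)
    abs(brute_u(pool[i], pool[-i]) - mu))
  mean(stats >= obs - 1e-9)
}

# Fisher two-sided p by full hypergeometric enumeration at fixed margins;
# the relative epsilon guards float comparison of equal-probability tables
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  x <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Welch statistic from the textbook formulae
welch_oracle <- function(x, y) {
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 /
    (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
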