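# Independent oracles: brute-force or closed-form implementations used only
# to verify results, never sharing code with the package internals.

## Pearson chi-square statistic straight from sum((O-E)^2/E)
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

## Fisher exact two-sided p for a 2x2 table by hypergeometric enumeration
fisher_2x2_oracle <- function(tab) {
  m <- rowSums(tab)[1]
  n <- rowSums(tab)[2]
  k <- colSums(tab)[1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Newton-Raphson fit of a log-link Poisson regression
poisson_nr_oracle <- function(y, X, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    mu <- as.vector(exp(X %*% beta))
    score <- crossprod(X, y - mu)
    info <- crossprod(X * mu, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.vector(beta)
}

## exhaustive best Gini bipartition of a categorical feature (binary y)
best_bipartition_oracle <- function(x, y) {
  lev <- sort(unique(as.character(x)))
  k <- length(lev)
  n <- length(y)
  gini_n <- function(idx) {
    nn <- sum(idx)
    if (nn == 0) return(0)
    pos <- sum(y[idx])
    2 * pos * (nn - pos) / nn
  }
  parent <- gini_n(rep(TRUE, n))
  best <- list(gain = -Inf, left = NULL)
  for (mask in 1:(2^(k - 1) - 1)) {
    left_lev <- lev[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    idx <- as.character(x) %in% left_lev
    gain <- parent - gini_n(idx) - gini_n(!idx)
    if (gain > best$gain + 1e-12) best <- list(gain = gain, left = left_lev)
  }
  best
}

## exhaustive best SSE split over all bipartitions (regression)
best_bipartition_sse_oracle <- function(x, y) {
  lev <- sort(unique(as.character(x)))
  k <- length(lev)
  sse <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  parent <- sse(y)
  best <- list(gain = -Inf, left = NULL)
  for (mask in 1:(2^(k - 1) - 1)) {
    left_lev <- lev[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    idx <- as.character(x) %in% left_lev
    gain <- parent - sse(y[idx]) - sse(y[!idx])
    if (gain > best$gain + 1e-12) best <- list(gain = gain, left = left_lev)
  }
  best
}

## Spearman rho by the direct rank formula
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## Kolmogorov distance between an empirical categorical distribution and
## its target probabilities
kolmogorov_cat <- function(counts, probs) {
  max(abs(cumsum(counts / sum(counts)) - cumsum(probs)))
}
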