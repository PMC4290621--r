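# Independent brute-force oracles used to check the analytical paths.

# Mann-Whitney two-sided p by full enumeration of all group assignments of
# the pooled values. U for group "x" counts pairs (xi > yj); two-sided p is
# the doubled smaller tail, capped at 1.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  us <- apply(utils::combn(length(pooled), n1), 2, u_of)
  u_obs <- u_of(seq_len(n1))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Hypergeometric upper tail by exhaustive enumeration of all n-subsets of a
# universe with K marked elements: P(#marked in subset >= k).
oracle_hyper_p <- function(N, K, n, k) {
  marked <- seq_len(K)
  subsets <- utils::combn(N, n)
  hits <- colSums(matrix(subsets %in% marked, nrow = n))
  mean(hits >= k)
}

# Kendall tau-b by O(n^2) pair counting with tie corrections.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  t1 <- sum(sapply(split(x, x), function(g)
    length(g) * (length(g) - 1) / 2))
  t2 <- sum(sapply(split(y, y), function(g)
    length(g) * (length(g) - 1) / 2))
  (C - D) / sqrt((n0 - t1) * (n0 - t2))
}

# Benjamini-Hochberg step-up computed literally from its definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, q_sorted)[order(o)]
}

# Unshrunken standardized nearest-centroid classifier, written directly.
oracle_nearest_centroid <- function(train, y, test) {
  y <- as.factor(y)
  classes <- levels(y)
  n <- ncol(train)
  cent <- sapply(classes, function(k)
    rowMeans(train[, y == k, drop = FALSE]))
  ss <- 0
  for (k in classes)
    ss <- ss + rowSums((train[, y == k, drop = FALSE] - cent[, k])^2)
  s <- sqrt(ss / (n - length(classes)))
  s0 <- stats::median(s)
  priors <- as.numeric(table(y)) / n
  scores <- sapply(seq_along(classes), function(k)
    colSums((test - cent[, k])^2 / (s + s0)^2) - 2 * log(priors[k]))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  classes[apply(scores, 1, which.min)]
}
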