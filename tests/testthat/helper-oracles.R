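# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with R/.

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n+m, n) group assignments of the observed values (midranks, so
# ties are handled naturally). Two-sided p doubles the smaller tail and
# caps at 1, matching the exact-test convention.
enum_wilcox_p <- function(xa, xb) {
  n <- length(xa)
  pooled <- c(xa, xb)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# AUROC by O(n^2) pairwise concordance: P(pos > neg) + 0.5 P(tie).
brute_auroc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Laplacian score via explicit dense D and L matrices and matrix
# quadratic forms.
dense_laplacian_score <- function(f, W) {
  D <- diag(rowSums(W))
  L <- D - W
  one <- rep(1, length(f))
  ft <- f - as.numeric((t(f) %*% D %*% one) / (t(one) %*% D %*% one)) * one
  num <- as.numeric(t(ft) %*% L %*% ft)
  den <- as.numeric(t(ft) %*% D %*% ft)
  if (den <= 1e-300) return(Inf)
  num / den
}

# Minimum within-cluster sum of squares over all partitions of the rows
# of x into exactly k non-empty clusters (exhaustive; tiny n only).
best_wss_exhaustive <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  assignments <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    if (length(unique(a)) != k) next
    wss <- 0
    for (c in unique(a)) {
      xc <- x[a == c, , drop = FALSE]
      mu <- colMeans(xc)
      wss <- wss + sum(sweep(xc, 2, mu)^2)
    }
    if (wss < best) best <- wss
  }
  best
}

wss_of <- function(x, assignments) {
  x <- as.matrix(x)
  tot <- 0
  for (c in unique(assignments)) {
    xc <- x[assignments == c, , drop = FALSE]
    tot <- tot + sum(sweep(xc, 2, colMeans(xc))^2)
  }
  tot
}
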