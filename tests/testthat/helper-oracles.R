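# Brute-force reference implementations, independent of the package's
# code paths, used to cross-check the statistical primitives.

oracleShannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

oracleBray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Step-up FDR adjustment evaluated literally from its definition:
# q_i = min over ranks j >= rank(i) of m * p_(j) / j, capped at 1.
oracleBH <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  sapply(seq_len(m), function(i) {
    js <- which(r >= r[i])
    min(pmin(1, m * p[js] / r[js]))
  })
}

# Naive O(n^3) complete-linkage agglomeration: returns sorted merge
# heights. Recomputes every inter-cluster distance from scratch at each
# step.
oracleCompleteHeights <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(D[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# Best rank-2 Frobenius reconstruction error of a matrix, via the
# eigendecomposition of the cross-product (Eckart-Young), not svd().
oracleRank2Error <- function(z) {
  ev <- eigen(crossprod(z), symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(0, sum(z^2) - sum(ev[1:2])))
}

randomDistMatrix <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 1)
  m <- m + t(m)
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  m
}
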