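# Independent oracles used to cross-check the package's implementations.

# Slow Sinkhorn-Knopp balancing: alternate row/column normalization of the
# full matrix until both sums are within `tol` of 1, then symmetrize. Kept
# deliberately independent of the Knight-Ruiz code path.
sinkhorn_balance <- function(M, tol = 1e-12, max_iter = 1e5) {
  P <- M
  for (it in seq_len(max_iter)) {
    P <- P / rowSums(P)
    P <- t(t(P) / colSums(P))
    if (max(abs(rowSums(P) - 1)) < tol && max(abs(colSums(P) - 1)) < tol) break
  }
  (P + t(P)) / 2
}

# Brute-force adjusted Rand index by counting all C(n,2) locus pairs:
# n11 pairs co-clustered in both labelings, n00 in neither, n10/n01 in one.
ari_pair_count <- function(a, b) {
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  n11 <- sum(same_a[ut] & same_b[ut])
  n00 <- sum(!same_a[ut] & !same_b[ut])
  n10 <- sum(same_a[ut] & !same_b[ut])
  n01 <- sum(!same_a[ut] & same_b[ut])
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / denom
}

# Random symmetric doubly stochastic matrix (balanced by the Sinkhorn oracle,
# not by the package's KR code).
random_doubly_stochastic <- function(n, seed) {
  M <- withr::with_seed(seed, {
    W <- matrix(stats::runif(n * n, 0.1, 1), n)
    (W + t(W)) / 2
  })
  sinkhorn_balance(M)
}

# Random positive symmetric matrix (not balanced).
random_symmetric <- function(n, seed, min = 0.1, max = 5) {
  withr::with_seed(seed, {
    W <- matrix(stats::runif(n * n, min, max), n)
    (W + t(W)) / 2
  })
}

# Random contiguous partition labels over n loci.
random_labels <- function(n, k, seed) {
  withr::with_seed(seed, {
    cuts <- sort(sample.int(n - 1L, k - 1L))
    rep.int(seq_len(k), diff(c(0L, cuts, n)))
  })
}
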