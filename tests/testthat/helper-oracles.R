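# Independent oracles, kept deliberately separate from the implementation
# paths they check.

# Weir-Cockerham theta via the nested-ANOVA mean-squares formulation
# (alleles within individuals within populations), computed from raw dosage
# vectors.  Returns the variance components and theta.
oracle_wc_anova <- function(dos1, dos2) {
  dos1 <- dos1[!is.na(dos1)]; dos2 <- dos2[!is.na(dos2)]
  dos <- list(dos1, dos2); r <- 2
  n <- vapply(dos, length, numeric(1))
  if (any(n < 1)) return(list(a = NA, b = NA, c = NA, theta = NA))
  p <- vapply(dos, function(d) mean(d) / 2, numeric(1))
  N <- sum(n)
  pbar <- sum(n * p) / N
  SSP <- sum(2 * n * (p - pbar)^2)
  SSI <- sum(unlist(mapply(function(d, pi) 2 * (d / 2 - pi)^2, dos, p)))
  SSG <- sum(vapply(dos, function(d) sum(d == 1), numeric(1))) / 2
  MSP <- SSP / (r - 1)
  MSI <- if (N - r > 0) SSI / (N - r) else 0
  MSG <- SSG / N
  nc <- (N - sum(n^2) / N) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  th <- if ((a + b + cc) != 0) a / (a + b + cc) else NA_real_
  list(a = a, b = b, c = cc, theta = th)
}

# Brute-force SNP-cluster filter: slide a window_bp-long span over every
# possible placement; any span holding more than max_snps SNPs marks all of
# its SNPs for removal.  Positions must belong to one chromosome.
oracle_cluster_drop <- function(pos, window_bp = 10, max_snps = 3) {
  drop <- rep(FALSE, length(pos))
  if (length(pos) == 0) return(drop)
  for (s in (min(pos) - window_bp):max(pos)) {
    inside <- pos >= s & pos <= s + window_bp - 1
    if (sum(inside) > max_snps) drop[inside] <- TRUE
  }
  drop
}

# Benjamini-Hochberg step-up, from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact hypergeometric upper tail P(X >= k) by enumeration of all C(N, n)
# draws (N small).
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  inset <- seq_len(K)  # the K set members are items 1..K
  hits <- apply(draws, 2, function(d) sum(d %in% inset))
  mean(hits >= k)
}

# Hypergeometric upper tail by direct summation of the pmf.
oracle_hyper_sum <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
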