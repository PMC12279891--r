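# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# Pearson chi-square statistic from the textbook formula.
oracle_chisq_stat <- function(O) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration over all tables with the observed margins.
oracle_fisher_2x2 <- function(O) {
  r <- rowSums(O); c <- colSums(O); N <- sum(O)
  a_range <- max(0, c[1] - r[2]):min(r[1], c[1])
  probs <- vapply(a_range, function(a) {
    stats::dhyper(a, r[1], r[2], c[1])
  }, numeric(1))
  p_obs <- stats::dhyper(O[1, 1], r[1], r[2], c[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by direct implementation of the rule.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Expected log1p(normalized) value of an NB(mu, size) count under a fixed
# library size, by summing the mass function.
oracle_expected_lognorm <- function(mu, size, lib, scale = 1e4, kmax = 2000) {
  k <- 0:kmax
  sum(stats::dnbinom(k, size = size, mu = mu) * log1p(k * scale / lib))
}

# Cosine of two numeric vectors, written independently.
oracle_cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
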