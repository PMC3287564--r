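# Exact two-sided p-value kernels shared by the user-facing tests and the
# Monte-Carlo engine. Both use the minimum-likelihood rule: sum the null
# probabilities of all outcomes whose point probability does not exceed the
# observed one. Point probabilities are compared with a 1 + 1e-7 relative
# slack so floating-point noise cannot split exact ties (the rule
# stats::binom.test and stats::fisher.test apply).

# Minimum-likelihood two-sided p-value of x for X ~ Bin(size, prob).
# Vectorised over x/size (prob scalar); outcomes are enumerated once per
# unique size, so long vectors sharing few distinct conditioning totals
# (the Monte-Carlo case) stay cheap.
pvalue_minlik_binom <- function(x, size, prob, rel_tol = 1e-7) {
  stopifnot(length(prob) == 1L, prob > 0, prob < 1)
  size <- rep_len(size, length(x))
  out <- numeric(length(x))
  for (k in unique(size)) {
    idx <- which(size == k)
    d <- dbinom(0:k, k, prob)
    o <- order(d)
    cum <- cumsum(d[o])
    # number of sorted point probabilities <= P(observed) * (1 + rel_tol)
    pos <- findInterval(d[x[idx] + 1L] * (1 + rel_tol), d[o])
    out[idx] <- pmin(1, cum[pos])
  }
  out
}

# Doubled smaller tail: min(1, 2 * min(P(X <= x), P(X >= x))).
pvalue_doubled_binom <- function(x, size, prob) {
  lo <- pbinom(x, size, prob)
  hi <- pbinom(x - 1L, size, prob, lower.tail = FALSE)
  pmin(1, 2 * pmin(lo, hi))
}

# Minimum-likelihood two-sided p-value of x for
# X ~ Hypergeometric(m white, n black, k drawn). The support has at most
# k + 1 points even when m, n are millions of reads, so enumeration is
# exact and cheap; work is grouped over unique (m, n, k).
pvalue_minlik_hyper <- function(x, m, n, k, rel_tol = 1e-7) {
  if (length(x) == 0L) return(numeric())
  len <- max(length(x), length(m), length(n), length(k))
  x <- rep_len(x, len); m <- rep_len(m, len)
  n <- rep_len(n, len); k <- rep_len(k, len)
  out <- numeric(len)
  key <- paste(m, n, k)
  for (g in unique(key)) {
    idx <- which(key == g)
    mi <- m[idx[1L]]; ni <- n[idx[1L]]; ki <- k[idx[1L]]
    lo <- max(0, ki - ni)
    d <- dhyper(lo:min(ki, mi), mi, ni, ki)
    o <- order(d)
    cum <- cumsum(d[o])
    pos <- findInterval(d[x[idx] - lo + 1L] * (1 + rel_tol), d[o])
    out[idx] <- pmin(1, cum[pos])
  }
  out
}

pvalue_doubled_hyper <- function(x, m, n, k) {
  lo <- phyper(x, m, n, k)
  hi <- phyper(x - 1, m, n, k, lower.tail = FALSE)
  pmin(1, 2 * pmin(lo, hi))
}
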