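# Independent brute-force oracles, written as plain per-instance loops so
# they share no code path with the package's grouped/vectorised kernels.

# minimum-likelihood two-sided binomial p-value by naive enumeration
naive_minlik_binom <- function(x, k, p0) {
  d <- vapply(0:k, function(j) dbinom(j, k, p0), 0)
  obs <- d[x + 1L]
  sum(d[d <= obs * (1 + 1e-7)])
}

# minimum-likelihood two-sided hypergeometric p-value by naive enumeration
# over every table with the observed margins
naive_minlik_hyper <- function(x, M1, M2, k) {
  supp <- max(0, k - M2):min(k, M1)
  d <- vapply(supp, function(j) dhyper(j, M1, M2, k), 0)
  obs <- d[match(x, supp)]
  sum(d[d <= obs * (1 + 1e-7)])
}

# exact rejection probability of a method by enumerating the joint
# distribution of the two condition sums (Poisson(n1*l1), Poisson(n2*l2))
exact_rejection_rate <- function(l1, l2, n1, n2, method, alpha = 1e-3,
                                 qmax = 400) {
  s <- 0:qmax
  w1 <- dpois(s, n1 * l1)
  w2 <- dpois(s, n2 * l2)
  S1 <- rep(s, times = length(s))
  S2 <- rep(s, each = length(s))
  p <- poisdeg:::method_pvalues(method, S1, S2, n1, n2, 1e6)$p
  sum((rep(w1, times = length(s)) * rep(w2, each = length(s)))[p < alpha])
}
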