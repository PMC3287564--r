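# Six tests for H0: lambda1 = lambda2 given replicate Poisson counts
# X_1j ~ Poi(lambda1), j = 1..n1 and X_2j ~ Poi(lambda2), j = 1..n2.
# All statistics depend on the data only through the condition sums
# S1 = sum_j X_1j and S2 = sum_j X_2j (plus lane totals for Fisher).
# Internal *_kernel functions are vectorised over (S1, S2) and feed both
# the user-facing tests below and the Monte-Carlo engine.

#' Canonical method names
#'
#' The six supported two-sample Poisson tests, in the canonical reporting
#' order used throughout the package: `"LRT"` (likelihood ratio),
#' `"Cond"` (conditional binomial exact), `"Wald"`, `"WaldLog"` (Wald on
#' the log fold change), `"VST"` (variance-stabilizing square-root
#' transformation) and `"Fisher"` (exact test on the 2x2 read-count table).
#'
#' @return Character vector of the six method labels.
#' @export
#' @examples
#' pois_methods()
pois_methods <- function() {
  c("LRT", "Cond", "Wald", "WaldLog", "VST", "Fisher")
}

check_counts <- function(x, arg) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop(sprintf("'%s' must be a non-empty numeric vector of counts", arg),
         call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop(sprintf("'%s' must contain finite non-negative integer counts", arg),
         call. = FALSE)
  }
  invisible(x)
}

# ---- vectorised statistic/p-value kernels -------------------------------

lrt_kernel <- function(S1, S2, n1, n2) {
  lam0 <- (S1 + S2) / (n1 + n2)
  # mean-difference terms n1(lam0 - lam1) + n2(lam0 - lam2) vanish
  # identically because lam0 is the pooled average of the lane counts
  t1 <- ifelse(S1 > 0, S1 * log(S1 / (n1 * lam0)), 0)
  t2 <- ifelse(S2 > 0, S2 * log(S2 / (n2 * lam0)), 0)
  stat <- pmax(2 * (t1 + t2), 0)
  list(statistic = stat,
       p.value = pchisq(stat, df = 1, lower.tail = FALSE),
       note = rep.int(NA_character_, length(stat)))
}

wald_kernel <- function(S1, S2, n1, n2) {
  r <- n1 / n2
  stat <- ifelse(S1 + S2 > 0, (S1 - r * S2) / sqrt(r * (S1 + S2)), NA_real_)
  list(statistic = stat,
       p.value = ifelse(is.na(stat), 1, 2 * pnorm(-abs(stat))),
       note = ifelse(is.na(stat), "no counts", NA_character_))
}

wald_log_kernel <- function(S1, S2, n1, n2, exponent_k = 2,
                            zero_correction = c("none", "pseudo")) {
  zero_correction <- match.arg(zero_correction)
  if (!(is.infinite(exponent_k) || exponent_k >= 2)) {
    stop("'exponent_k' must be >= 2 or Inf", call. = FALSE)
  }
  zero <- S1 == 0 | S2 == 0
  if (zero_correction == "pseudo") {
    # add half a count to both sums whenever either is empty
    S1 <- ifelse(zero, S1 + 0.5, S1)
    S2 <- ifelse(zero, S2 + 0.5, S2)
    zero <- rep.int(FALSE, length(S1))
  }
  logfc <- log((S1 / n1) / (S2 / n2))
  v <- (2 + n1 / n2 + n2 / n1) / (S1 + S2)
  denom <- if (is.infinite(exponent_k)) 1 else v^(1 / exponent_k)
  stat <- ifelse(zero, NA_real_, logfc / denom)
  p <- if (exponent_k == 2) {
    ifelse(zero, 1, 2 * pnorm(-abs(stat)))
  } else {
    # generalized exponent: a ranking score with no reference distribution
    ifelse(zero, 1, NA_real_)
  }
  list(statistic = stat, p.value = p,
       note = ifelse(zero, "zero sum", NA_character_))
}

vst_kernel <- function(S1, S2, n1, n2) {
  stat <- 2 * (sqrt(S1 + 3 / 8) - sqrt((S2 + 3 / 8) * n1 / n2)) /
    sqrt(1 + n1 / n2)
  list(statistic = stat, p.value = 2 * pnorm(-abs(stat)),
       note = rep.int(NA_character_, length(stat)))
}

cond_kernel <- function(S1, S2, n1, n2,
                        method = c("min_likelihood", "doubled_tail")) {
  method <- match.arg(method)
  k <- S1 + S2
  p0 <- n1 / (n1 + n2)
  empty <- k == 0
  p <- numeric(length(k))
  if (any(!empty)) {
    p[!empty] <- if (method == "min_likelihood") {
      pvalue_minlik_binom(S1[!empty], k[!empty], p0)
    } else {
      pvalue_doubled_binom(S1[!empty], k[!empty], p0)
    }
  }
  p[empty] <- 1
  list(statistic = ifelse(empty, NA_real_, S1),
       p.value = p,
       note = ifelse(empty, "no counts", NA_character_))
}

fisher_kernel <- function(S1, S2, M1, M2,
                          method = c("min_likelihood", "doubled_tail")) {
  method <- match.arg(method)
  if (any(M1 < S1) || any(M2 < S2)) {
    stop("lane totals smaller than gene counts: 2x2 cells must be non-negative",
         call. = FALSE)
  }
  k <- S1 + S2
  p <- if (method == "min_likelihood") {
    pvalue_minlik_hyper(S1, M1, M2, k)
  } else {
    pvalue_doubled_hyper(S1, M1, M2, k)
  }
  list(statistic = S1, p.value = p,
       note = rep.int(NA_character_, length(S1)))
}

# ---- user-facing tests --------------------------------------------------

pois_htest <- function(kern, method, dname, extra = NULL) {
  out <- c(list(
    statistic = c(statistic = kern$statistic[1L]),
    p.value = kern$p.value[1L],
    method = method,
    data.name = dname,
    note = kern$note[1L]
  ), extra)
  class(out) <- c("pois_htest", "htest")
  out
}

#' @export
print.pois_htest <- function(x, ...) {
  cl <- x
  class(cl) <- "htest"
  print(cl, ...)
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Likelihood ratio test for two Poisson means
#'
#' Tests whether the per-lane Poisson rates of two conditions differ, from
#' the replicate counts of a single gene. With condition sums `S1`, `S2`
#' over `n1`, `n2` lanes, the deviance statistic is
#' \deqn{T = 2[S_1 \log(\hat\lambda_1/\hat\lambda_0) +
#'            S_2 \log(\hat\lambda_2/\hat\lambda_0)],}
#' where \eqn{\hat\lambda_i = S_i/n_i} and
#' \eqn{\hat\lambda_0 = (S_1+S_2)/(n_1+n_2)}; under the null it is
#' asymptotically chi-square with 1 degree of freedom, and the p-value is
#' the upper tail. Zero sums contribute 0 to the statistic; with no counts
#' at all the statistic is 0 and p = 1.
#'
#' @param counts1,counts2 Non-negative integer vectors: read counts per
#'   lane (technical replicate) under each condition.
#' @return An object of class `c("pois_htest", "htest")` with the
#'   statistic, p-value and rate estimates.
#' @seealso [wald_test], [wald_log_test], [vst_test], [cond_binom_test],
#'   [fisher_lane_test], [run_all_tests]
#' @export
#' @examples
#' lrt_test(20, 5)
#' lrt_test(c(3, 5, 4), c(9, 11, 13))
lrt_test <- function(counts1, counts2) {
  check_counts(counts1, "counts1"); check_counts(counts2, "counts2")
  S1 <- sum(counts1); S2 <- sum(counts2)
  n1 <- length(counts1); n2 <- length(counts2)
  kern <- lrt_kernel(S1, S2, n1, n2)
  pois_htest(kern, "Two-sample Poisson likelihood ratio test",
             paste(deparse1(substitute(counts1)), "and",
                   deparse1(substitute(counts2))),
             extra = list(estimate = c(`rate 1` = S1 / n1, `rate 2` = S2 / n2),
                          parameter = c(df = 1)))
}

#' Conditional binomial exact test for two Poisson means
#'
#' Conditional on the total count `k = S1 + S2`, the condition-1 sum of
#' Poisson lane counts is binomial, `S1 | k ~ Bin(k, p)` with
#' `p = n1*lambda1 / (n1*lambda1 + n2*lambda2)`, so under the null
#' `p0 = n1/(n1+n2)` and an exact p-value is available without asymptotics.
#' The default two-sided rule is minimum-likelihood: the sum of `Bin(k, p0)`
#' probabilities over all outcomes no more probable than the observed `S1`.
#' `"doubled_tail"` instead doubles the smaller tail probability.
#'
#' @inheritParams lrt_test
#' @param method Two-sided rule: `"min_likelihood"` (default) or
#'   `"doubled_tail"`.
#' @return A `c("pois_htest", "htest")` object; the statistic slot carries
#'   the observed `S1`. With `k = 0` the statistic is undefined and p = 1
#'   (no information against the null).
#' @export
#' @examples
#' cond_binom_test(20, 5)
#' cond_binom_test(c(0), c(2, 2, 2, 2), method = "min_likelihood")
cond_binom_test <- function(counts1, counts2,
                            method = c("min_likelihood", "doubled_tail")) {
  check_counts(counts1, "counts1"); check_counts(counts2, "counts2")
  method <- match.arg(method)
  kern <- cond_kernel(sum(counts1), sum(counts2),
                      length(counts1), length(counts2), method = method)
  names(kern$statistic) <- NULL
  out <- pois_htest(kern, sprintf(
    "Conditional binomial exact test for two Poisson means (%s)", method),
    paste(deparse1(substitute(counts1)), "and",
          deparse1(substitute(counts2))))
  names(out$statistic) <- "S1"
  out
}

#' Wald test for two Poisson means
#'
#' Normal-approximation test on the difference of condition sums:
#' \deqn{T = \frac{S_1 - (n_1/n_2) S_2}{\sqrt{(n_1/n_2)(S_1+S_2)}},}
#' asymptotically standard normal under the null; the p-value is
#' two-sided. With `S1 + S2 = 0` the statistic is undefined and p = 1.
#'
#' @inheritParams lrt_test
#' @return A `c("pois_htest", "htest")` object.
#' @export
#' @examples
#' wald_test(20, 5)
wald_test <- function(counts1, counts2) {
  check_counts(counts1, "counts1"); check_counts(counts2, "counts2")
  kern <- wald_kernel(sum(counts1), sum(counts2),
                      length(counts1), length(counts2))
  pois_htest(kern, "Two-sample Poisson Wald test",
             paste(deparse1(substitute(counts1)), "and",
                   deparse1(substitute(counts2))))
}

#' Wald test on the log fold change (Wald-Log)
#'
#' Applies the Wald test to log-transformed rates via the delta method.
#' With fold change `FC = (S1/n1)/(S2/n2)`,
#' \deqn{T = \frac{\log FC}{\sqrt{(2 + n_1/n_2 + n_2/n_1)/(S_1+S_2)}},}
#' asymptotically standard normal; the denominator is the estimated
#' standard error of the log fold change, which ties the test directly to
#' the fold-change scale biologists screen on. The p-value is two-sided.
#'
#' `exponent_k` generalizes the denominator to the `1/k` power of the same
#' variance term. `exponent_k = 2` is the Wald-Log test; as
#' `exponent_k -> Inf` the denominator tends to 1 and the statistic becomes
#' the log fold change itself, i.e. a pure fold-change ranking criterion.
#' For `exponent_k != 2` no reference distribution applies, so the p-value
#' is `NA` and the statistic is a ranking score only. (This `k` is the
#' denominator exponent, not the conditioning total `k = S1 + S2` of
#' [cond_binom_test].)
#'
#' @inheritParams lrt_test
#' @param exponent_k Denominator exponent, a real `>= 2` or `Inf`;
#'   default 2.
#' @param zero_correction With `"none"` (default), a zero condition sum
#'   leaves `log(FC)` undefined: the statistic is `NA` and p = 1 (never
#'   reject). `"pseudo"` instead adds 0.5 to both sums when either is zero.
#' @return A `c("pois_htest", "htest")` object.
#' @export
#' @examples
#' wald_log_test(20, 5)
#' wald_log_test(20, 5, exponent_k = Inf)  # log fold change itself
wald_log_test <- function(counts1, counts2, exponent_k = 2,
                          zero_correction = c("none", "pseudo")) {
  check_counts(counts1, "counts1"); check_counts(counts2, "counts2")
  kern <- wald_log_kernel(sum(counts1), sum(counts2),
                          length(counts1), length(counts2),
                          exponent_k = exponent_k,
                          zero_correction = match.arg(zero_correction))
  S1 <- sum(counts1); S2 <- sum(counts2)
  n1 <- length(counts1); n2 <- length(counts2)
  fc <- if (S2 > 0 && S1 > 0) (S1 / n1) / (S2 / n2) else NA_real_
  pois_htest(kern, "Two-sample Poisson Wald test on the log fold change",
             paste(deparse1(substitute(counts1)), "and",
                   deparse1(substitute(counts2))),
             extra = list(estimate = c(`fold change` = fc)))
}

#' Variance-stabilizing transformation test for two Poisson means
#'
#' The square-root transform `sqrt(S + 3/8)` of a Poisson count has
#' approximately constant variance 1/4 (Anscombe), so
#' \deqn{T = \frac{2[\sqrt{S_1 + 3/8} - \sqrt{(S_2 + 3/8)\, n_1/n_2}]}
#'               {\sqrt{1 + n_1/n_2}}}
#' is asymptotically standard normal under the null. The p-value is
#' two-sided. The 3/8 anchor keeps the statistic defined for zero counts.
#'
#' @inheritParams lrt_test
#' @return A `c("pois_htest", "htest")` object.
#' @export
#' @examples
#' vst_test(20, 5)
#' vst_test(0, 0)  # defined even with no reads
vst_test <- function(counts1, counts2) {
  check_counts(counts1, "counts1"); check_counts(counts2, "counts2")
  kern <- vst_kernel(sum(counts1), sum(counts2),
                     length(counts1), length(counts2))
  pois_htest(kern,
             "Two-sample Poisson variance-stabilizing transformation test",
             paste(deparse1(substitute(counts1)), "and",
                   deparse1(substitute(counts2))))
}

#' Fisher exact test on the 2x2 read-count table
#'
#' Builds the 2x2 table whose rows are the two conditions and whose columns
#' are (reads in this gene, all other reads on the lanes): row i is
#' `(S_i, M_i - S_i)` with `M_i` the summed lane totals of condition i.
#' Conditional on the margins the gene count of condition 1 is
#' hypergeometric, giving an exact p-value; the default two-sided rule is
#' minimum-likelihood over the hypergeometric support (sum of
#' probabilities of all tables no more probable than the observed one).
#'
#' When lane totals are much larger than the gene counts the hypergeometric
#' converges to `Bin(S1 + S2, n1/(n1+n2))` and this test coincides with
#' [cond_binom_test].
#'
#' @inheritParams cond_binom_test
#' @param totals1,totals2 Positive integer vectors of per-lane total mapped
#'   reads, pairing with `counts1`, `counts2` (each total must be at least
#'   its lane's gene count).
#' @return A `c("pois_htest", "htest")` object; the statistic slot carries
#'   the observed `S1`.
#' @export
#' @examples
#' fisher_lane_test(20, 5, totals1 = 1e6, totals2 = 1e6)
fisher_lane_test <- function(counts1, counts2, totals1, totals2,
                             method = c("min_likelihood", "doubled_tail")) {
  check_counts(counts1, "counts1"); check_counts(counts2, "counts2")
  check_counts(totals1, "totals1"); check_counts(totals2, "totals2")
  method <- match.arg(method)
  if (length(totals1) != length(counts1) && length(totals1) != 1L ||
      length(totals2) != length(counts2) && length(totals2) != 1L) {
    stop("lane totals must pair with the count vectors (or be a single sum)",
         call. = FALSE)
  }
  if (any(rep_len(totals1, length(counts1)) < counts1 & length(totals1) > 1L) ||
      any(rep_len(totals2, length(counts2)) < counts2 & length(totals2) > 1L)) {
    stop("each lane total must be >= the lane's gene count", call. = FALSE)
  }
  kern <- fisher_kernel(sum(counts1), sum(counts2),
                        sum(totals1), sum(totals2), method = method)
  out <- pois_htest(kern, sprintf(
    "Fisher exact test on the 2x2 read-count table (%s)", method),
    paste(deparse1(substitute(counts1)), "and",
          deparse1(substitute(counts2))))
  names(out$statistic) <- "S1"
  out
}

#' Run all requested tests on one gene's counts
#'
#' Applies any subset of the six two-sample Poisson tests to the same
#' replicate counts and collects one row per method, in the canonical
#' order [pois_methods()]. Degenerate inputs (zero sums) never abort: the
#' affected method reports an undefined statistic with p = 1 and a note.
#'
#' @inheritParams lrt_test
#' @param totals1,totals2 Per-lane totals for the Fisher test; required iff
#'   `"Fisher"` is among `methods`.
#' @param methods Subset of [pois_methods()].
#' @param cond_method Two-sided rule passed to the exact tests.
#' @return A data frame with columns `method`, `statistic`, `p.value`,
#'   `note`, one row per requested method.
#' @export
#' @examples
#' run_all_tests(20, 5, totals1 = 1e6, totals2 = 1e6)
#' run_all_tests(c(1, 2), c(8, 9), methods = c("LRT", "WaldLog"))
run_all_tests <- function(counts1, counts2, totals1 = NULL, totals2 = NULL,
                          methods = pois_methods(),
                          cond_method = c("min_likelihood", "doubled_tail")) {
  check_counts(counts1, "counts1"); check_counts(counts2, "counts2")
  cond_method <- match.arg(cond_method)
  if (length(methods) == 0L) {
    return(data.frame(method = character(), statistic = numeric(),
                      p.value = numeric(), note = character(),
                      stringsAsFactors = FALSE))
  }
  methods <- match.arg(methods, pois_methods(), several.ok = TRUE)
  methods <- pois_methods()[pois_methods() %in% methods]
  if ("Fisher" %in% methods && (is.null(totals1) || is.null(totals2))) {
    stop("Fisher test requires lane totals 'totals1' and 'totals2'",
         call. = FALSE)
  }
  S1 <- sum(counts1); S2 <- sum(counts2)
  n1 <- length(counts1); n2 <- length(counts2)
  one <- function(m) {
    kern <- switch(m,
      LRT = lrt_kernel(S1, S2, n1, n2),
      Cond = cond_kernel(S1, S2, n1, n2, method = cond_method),
      Wald = wald_kernel(S1, S2, n1, n2),
      WaldLog = wald_log_kernel(S1, S2, n1, n2),
      VST = vst_kernel(S1, S2, n1, n2),
      Fisher = fisher_kernel(S1, S2, sum(totals1), sum(totals2),
                             method = cond_method))
    data.frame(method = m, statistic = kern$statistic,
               p.value = kern$p.value, note = kern$note,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(methods, one))
  rownames(out) <- NULL
  out
}
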