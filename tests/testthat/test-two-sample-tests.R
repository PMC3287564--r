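# Worked-example values frozen from independent hand/enumeration oracles:
# for (S1, S2, n1, n2) = (20, 5, 1, 1),
#   T_Wald    = 15 / sqrt(25)                        = 3
#   T_WaldLog = log(4) / sqrt((2 + 1 + 1) / 25)      = 3.465736...
#   T_VST     = 2 (sqrt(20.375) - sqrt(5.375)) / sqrt(2) = 3.104853...
#   T_LRT     = 2 [20 log(20/12.5) + 5 log(5/12.5)]  = 9.637238...
#   p_Cond    = 2 * P(X >= 20), X ~ Bin(25, 1/2)     = 2 * 68406 / 2^25

test_that("statistics and p-values match the hand-derived worked example", {
  expect_equal(wald_test(20, 5)$statistic, c(statistic = 3), tolerance = 1e-12)
  expect_equal(unname(wald_log_test(20, 5)$statistic),
               log(4) / sqrt(4 / 25), tolerance = 1e-12)
  expect_equal(unname(wald_log_test(20, 5)$statistic), 3.465736,
               tolerance = 1e-6)
  expect_equal(unname(vst_test(20, 5)$statistic),
               2 * (sqrt(20.375) - sqrt(5.375)) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(vst_test(20, 5)$statistic), 3.104853, tolerance = 1e-6)
  expect_equal(unname(lrt_test(20, 5)$statistic),
               2 * (20 * log(20 / 12.5) + 5 * log(5 / 12.5)),
               tolerance = 1e-12)
  expect_equal(unname(lrt_test(20, 5)$statistic), 9.637238, tolerance = 1e-6)
  expect_equal(lrt_test(20, 5)$p.value,
               pchisq(9.637238, 1, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(cond_binom_test(20, 5)$p.value, 2 * 68406 / 2^25,
               tolerance = 1e-12)
  expect_equal(cond_binom_test(20, 5, method = "doubled_tail")$p.value,
               2 * 68406 / 2^25, tolerance = 1e-12)
  expect_equal(wald_log_test(20, 5)$p.value,
               2 * pnorm(-3.465736), tolerance = 1e-6)
})

test_that("equal observed rates give a zero statistic and p = 1", {
  for (case in list(list(10, 10), list(c(5, 5, 5), c(5, 5, 5)))) {
    for (f in list(lrt_test, wald_test, wald_log_test, vst_test)) {
      out <- f(case[[1]], case[[2]])
      expect_equal(out$p.value, 1)
      expect_equal(unname(out$statistic), 0, tolerance = 1e-12)
    }
    expect_equal(cond_binom_test(case[[1]], case[[2]])$p.value, 1)
  }
  # equal per-lane rates, unequal lane counts: LRT/Wald/WaldLog still null
  # (VST is only asymptotically centred here because of the 3/8 anchor)
  for (f in list(lrt_test, wald_test, wald_log_test)) {
    expect_equal(unname(f(c(10, 20), c(15, 15, 15))$statistic), 0,
                 tolerance = 1e-12)
  }
  # equal per-lane rates with unequal lane counts: Wald numerator cancels
  expect_equal(unname(wald_test(c(15, 15), c(15, 15, 15))$statistic), 0)
})

test_that("swapping the samples negates normal statistics and keeps p-values", {
  set.seed(1)
  for (i in 1:25) {
    n <- sample(1:4, 1)
    x <- rpois(n, sample(3:30, 1))
    y <- rpois(n, sample(3:30, 1))
    for (f in list(wald_test, wald_log_test, vst_test)) {
      a <- f(x, y); b <- f(y, x)
      if (!is.na(a$statistic) && !is.na(b$statistic)) {
        expect_equal(unname(a$statistic), -unname(b$statistic),
                     tolerance = 1e-9)
      }
      expect_equal(a$p.value, b$p.value, tolerance = 1e-9)
    }
    expect_equal(lrt_test(x, y)$statistic, lrt_test(y, x)$statistic,
                 tolerance = 1e-9)
    expect_equal(cond_binom_test(x, y)$p.value, cond_binom_test(y, x)$p.value,
                 tolerance = 1e-12)
    expect_equal(fisher_lane_test(x, y, rep(1000, n), rep(1000, n))$p.value,
                 fisher_lane_test(y, x, rep(1000, n), rep(1000, n))$p.value,
                 tolerance = 1e-12)
  }
})

test_that("LRT statistic is a non-negative deviance", {
  set.seed(2)
  for (i in 1:50) {
    x <- rpois(sample(1:3, 1), runif(1, 0.2, 40))
    y <- rpois(sample(1:3, 1), runif(1, 0.2, 40))
    expect_gte(unname(lrt_test(x, y)$statistic), 0)
  }
})

test_that("zero-sum inputs follow the never-reject convention", {
  wl <- wald_log_test(0, 7)
  expect_true(is.na(wl$statistic))
  expect_equal(wl$p.value, 1)
  expect_equal(wl$note, "zero sum")

  w <- wald_test(0, 0)
  expect_true(is.na(w$statistic))
  expect_equal(w$p.value, 1)

  cb <- cond_binom_test(0, 0)
  expect_true(is.na(cb$statistic))
  expect_equal(cb$p.value, 1)
  expect_equal(cb$note, "no counts")

  v <- vst_test(0, 0)          # the 3/8 anchor keeps VST defined
  expect_equal(unname(v$statistic), 0)
  expect_equal(v$p.value, 1)

  # pseudo-count mode gives a finite statistic instead
  wl2 <- wald_log_test(0, 7, zero_correction = "pseudo")
  expect_false(is.na(wl2$statistic))
  expect_lt(wl2$p.value, 1)
})

test_that("generalized denominator exponent interpolates to the fold change", {
  # exponent Inf: denominator 1, statistic = log fold change, no p-value
  inf <- wald_log_test(20, 5, exponent_k = Inf)
  expect_equal(unname(inf$statistic), log(4), tolerance = 1e-12)
  expect_true(is.na(inf$p.value))
  k4 <- wald_log_test(20, 5, exponent_k = 4)
  expect_equal(unname(k4$statistic), log(4) / (4 / 25)^(1 / 4),
               tolerance = 1e-12)
  expect_true(is.na(k4$p.value))
  expect_error(wald_log_test(20, 5, exponent_k = 1), "exponent_k")
})

test_that("asymptotic tests agree at large pooled rates", {
  for (s in list(c(1000, 1100), c(2000, 1900))) {
    ps <- c(lrt_test(s[1], s[2])$p.value, wald_test(s[1], s[2])$p.value,
            wald_log_test(s[1], s[2])$p.value, vst_test(s[1], s[2])$p.value)
    expect_lt(max(ps) / min(ps), 1.10)
  }
})

test_that("run_all_tests returns the canonical order and tolerates degeneracy", {
  out <- run_all_tests(20, 5, totals1 = 1e6, totals2 = 1e6)
  expect_equal(out$method, pois_methods())
  expect_true(all(out$p.value >= 0 & out$p.value <= 1))
  # individual tests and the combined runner agree
  expect_equal(out$p.value[out$method == "WaldLog"],
               wald_log_test(20, 5)$p.value)
  expect_equal(out$p.value[out$method == "Fisher"],
               fisher_lane_test(20, 5, 1e6, 1e6)$p.value)

  # degenerate gene: one method undefined, others still reported
  deg <- run_all_tests(0, 9, methods = c("LRT", "WaldLog", "VST"))
  expect_equal(nrow(deg), 3L)
  expect_equal(deg$p.value[deg$method == "WaldLog"], 1)
  expect_lt(deg$p.value[deg$method == "LRT"], 1)

  expect_equal(nrow(run_all_tests(3, 4, methods = character())), 0L)
  expect_error(run_all_tests(3, 4, methods = "Fisher"), "totals")
})

test_that("count vectors are validated", {
  expect_error(lrt_test(c(-1, 2), 3), "non-negative")
  expect_error(wald_test(1.5, 3), "integer")
  expect_error(vst_test(numeric(), 3), "non-empty")
  expect_error(fisher_lane_test(5, 5, totals1 = c(2, 2), totals2 = 10),
               "pair")
})
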