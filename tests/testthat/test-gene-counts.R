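# Count-matrix container, TSV parsing, filters, normalization, generator.

write_counts_fixture <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("a counts TSV round-trips through read_counts", {
  path <- write_counts_fixture(data.frame(
    gene = c("g1", "g2"), kidney1 = c(3, 0), liver1 = c(4, 9)))
  m <- read_counts(path, group1 = "kidney1", group2 = "liver1")
  expect_equal(unname(m$counts), matrix(c(3, 0, 4, 9), 2))
  expect_equal(m$gene_ids, c("g1", "g2"))
  expect_equal(m$condition, c(1L, 2L))
  expect_equal(m$lane_totals, c(kidney1 = 3, liver1 = 13))
})

test_that("parse errors name the offending cell or lane", {
  neg <- write_counts_fixture(data.frame(
    gene = c("g1", "g2"), a = c(3, -2), b = c(1, 1)))
  expect_error(read_counts(neg, group1 = "a", group2 = "b"),
               "gene 'g2', lane 'a'")
  frac <- write_counts_fixture(data.frame(gene = "g1", a = "2.5", b = "1"))
  expect_error(read_counts(frac, group1 = "a", group2 = "b"),
               "lane 'a'")
  dup <- write_counts_fixture(data.frame(
    gene = c("g1", "g1"), a = c(1, 2), b = c(3, 4)))
  expect_error(read_counts(dup, group1 = "a", group2 = "b"), "duplicate")
  ok <- write_counts_fixture(data.frame(gene = "g1", a = 1, b = 2, c = 3))
  expect_error(read_counts(ok, group1 = "a", group2 = "z"), "absent")
  expect_error(read_counts(ok, group1 = "a", group2 = "b"),
               "not assigned.*c")
})

test_that("condition file assigns lanes like group flags do", {
  path <- write_counts_fixture(data.frame(
    gene = c("g1", "g2"), a = c(5, 1), b = c(2, 2), c = c(0, 7)))
  cf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\t1", "b\t1", "c\t2"), cf)
  m1 <- read_counts(path, condition_file = cf)
  m2 <- read_counts(path, group1 = c("a", "b"), group2 = "c")
  expect_equal(m1$condition, m2$condition)
  expect_equal(m1$counts, m2$counts)
})

test_that("minimum-total filter uses per-condition sums with closed bounds", {
  counts <- rbind(g_keep = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
                  g_drop = c(1, 1, 1, 1, 0, rep(20, 5)),
                  g_zero = rep(0, 10))
  m <- gene_counts(counts, condition = rep(c(1, 2), each = 5))
  f <- filter_min_total(m, 5)
  # S1 = S2 = 5 sits exactly on the threshold and is kept;
  # S1 = 4 fails condition 1 even though S2 = 100
  expect_equal(f$gene_ids, "g_keep")
  expect_equal(filter_min_total(m, 0)$gene_ids, m$gene_ids)
  pooled <- filter_min_total(m, 5, scope = "pooled")
  expect_equal(pooled$gene_ids, c("g_keep", "g_drop"))
})

test_that("low-expression filter keeps the closed per-lane-average interval", {
  counts <- rbind(edge_lo_hi = c(rep(1, 5), rep(10, 5)),
                  below = c(rep(c(1, 1, 1, 1, 0), 1), rep(2, 5)),
                  above = c(rep(11, 5), rep(2, 5)))
  m <- gene_counts(counts, condition = rep(c(1, 2), each = 5))
  f <- filter_low_expression(m)
  expect_equal(f$gene_ids, "edge_lo_hi")  # averages exactly 1 and 10 kept
  expect_equal(filter_low_expression(m, 0, Inf)$gene_ids, m$gene_ids)
  expect_error(filter_low_expression(m, 5, 2), "lo")
})

test_that("global rescale equalizes lane totals and keeps integer counts", {
  m <- gene_counts(rbind(g1 = c(10, 30), g2 = c(90, 170)), c(1, 2))
  expect_equal(m$lane_totals, c(lane1 = 100, lane2 = 200))
  r <- global_rescale(m)
  # target 150: lane 1 scaled x1.5, lane 2 x0.75
  expect_equal(unname(r$counts), matrix(c(15, 135, 22, 128), 2))
  expect_true(all(r$counts == round(r$counts)))
  eq <- gene_counts(rbind(g1 = c(5, 5)), c(1, 2))
  expect_equal(global_rescale(eq)$counts, eq$counts)
})

test_that("constructor rejects invalid containers", {
  expect_error(gene_counts(rbind(c(1, 2)), condition = c(1, 1)),
               "labels 1 and 2")
  expect_error(gene_counts(rbind(c(1, 2), c(1, 2)), c(1, 2),
                           gene_ids = c("g", "g")), "duplicate")
  expect_error(gene_counts(rbind(c(1.5, 2)), c(1, 2)), "integer")
  expect_error(gene_counts(rbind(c(5, 2)), c(1, 2), lane_totals = c(1, 10)),
               "column sums")
})

test_that("synthetic generator reproduces its design and seed", {
  synth <- synth_matrix(500, deg_fraction = 0.2, fold_change = 4, seed = 42)
  expect_equal(dim(synth$counts), c(500L, 10L))
  expect_equal(length(synth$is_deg), 500L)
  # DEG labels match where the condition factor was applied
  expect_true(all(is.na(synth$deg_condition[!synth$is_deg])))
  expect_true(all(synth$deg_condition[synth$is_deg] %in% 1:2))
  # fraction close to requested
  expect_lt(abs(mean(synth$is_deg) - 0.2), 3 * sqrt(0.2 * 0.8 / 500))
  again <- synth_matrix(500, deg_fraction = 0.2, fold_change = 4, seed = 42)
  expect_identical(synth, again)
  expect_false(identical(
    synth$counts$counts,
    synth_matrix(500, deg_fraction = 0.2, fold_change = 4, seed = 43)$counts$counts))
  # true DEGs show elevated means in the labelled condition
  s <- poisdeg:::cond_sums(synth$counts)
  up1 <- which(synth$deg_condition == 1L)
  expect_gt(mean(s$S1[up1]) / mean(s$S2[up1]), 2)
  # degenerate designs
  expect_equal(dim(synth_matrix(0)$counts), c(0L, 10L))
  null <- synth_matrix(200, deg_fraction = 0, seed = 1)
  expect_false(any(null$is_deg))
})
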